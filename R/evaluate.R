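# Statistical evaluation harness: confusion matrices, per-class and
# support-weighted precision/recall/F1, accuracy, threshold-sweep ROC with
# trapezoidal AUC, one-vs-rest multiclass AUC averaging with per-class fold
# substitution and weight suppression, and the optimal decision point
# (fewest cumulative false positives plus false negatives).

#' Confusion matrix
#'
#' Rows are true labels, columns predictions; entries are frame counts. A
#' perfectly accurate model has counts only on the diagonal.
#'
#' @param truth,predicted Character vectors of class labels (equal length).
#' @param classes Ordered class vector; both label vectors must draw from it.
#' @return A `confusion_matrix` (integer matrix with class `confusion_matrix`).
#' @export
confusion_matrix <- function(truth, predicted, classes) {
  stopifnot(length(truth) == length(predicted))
  bad <- setdiff(unique(c(truth, predicted)), classes)
  if (length(bad)) {
    stop("label(s) outside the class set: ", paste(bad, collapse = ", "))
  }
  m <- table(factor(truth, levels = classes),
             factor(predicted, levels = classes))
  as_confusion_matrix(matrix(as.integer(m), nrow = length(classes),
                             dimnames = list(classes, classes)))
}

#' @rdname confusion_matrix
#' @param counts Square count matrix (rows = truth) with identical row and
#'   column names; used to load printed/archived matrices as fixtures.
#' @export
as_confusion_matrix <- function(counts) {
  stopifnot(is.matrix(counts), nrow(counts) == ncol(counts),
            all(counts >= 0),
            identical(rownames(counts), colnames(counts)))
  structure(counts, class = c("confusion_matrix", "matrix"))
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix>", sum(x), "frames\n")
  print(unclass(x))
  invisible(x)
}

#' Per-class precision, recall and F1
#'
#' `precision = TP / (TP + FP)`, `recall = TP / (TP + FN)`,
#' `F1 = 2 * precision * recall / (precision + recall)`. A class that is
#' never predicted gets precision 0 and is flagged.
#'
#' @param cm A [confusion_matrix()].
#' @return Tibble with `class, support, tp, precision, recall, f1,
#'   never_predicted`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(sum(cm) > 0)
  tp <- diag(cm)
  support <- rowSums(cm)
  predicted <- colSums(cm)
  precision <- ifelse(predicted == 0, 0, tp / predicted)
  recall <- ifelse(support == 0, 0, tp / support)
  f1 <- ifelse(precision + recall == 0, 0,
               2 * precision * recall / (precision + recall))
  tibble(class = rownames(cm), support = as.integer(support),
         tp = as.integer(tp), precision = unname(precision),
         recall = unname(recall), f1 = unname(f1),
         never_predicted = unname(predicted == 0))
}

#' Support-weighted metrics and accuracy
#'
#' Weighted averages of the per-class metrics with true-class supports as
#' weights, plus overall accuracy (`trace / total`). Under this definition
#' the weighted recall equals the accuracy identically.
#'
#' @param cm A [confusion_matrix()].
#' @return Named list `precision, recall, f1, accuracy`.
#' @export
weighted_metrics <- function(cm) {
  pc <- per_class_metrics(cm)
  w <- pc$support
  list(precision = weighted.mean(pc$precision, w),
       recall = weighted.mean(pc$recall, w),
       f1 = weighted.mean(pc$f1, w),
       accuracy = sum(diag(cm)) / sum(cm))
}

#' ROC curve by threshold sweep
#'
#' Sweeps thresholds over the unique scores (prediction is positive when
#' `score >= threshold`), recording TP/FP/TN/FN at every threshold. The curve
#' starts at (FPR, TPR) = (0, 0) (threshold above every score) and ends at
#' (1, 1).
#'
#' @param scores Numeric positive-class scores (probabilities or raw margins;
#'   ROC is rank-based so calibration is irrelevant).
#' @param labels Logical (or 0/1) true positives.
#' @return Tibble of class `roc_curve` with columns
#'   `threshold, tp, fp, tn, fn, fpr, tpr`, thresholds descending.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("roc_curve needs at least one positive and one negative instance")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  # cumulative counts at each unique score boundary
  last <- !duplicated(s, fromLast = TRUE)  # last index of each unique score
  tp <- cumsum(l)[last]
  fp <- cumsum(!l)[last]
  thr <- s[last]
  out <- tibble(threshold = c(Inf, thr),
                tp = as.integer(c(0, tp)), fp = as.integer(c(0, fp)))
  out$tn <- n0 - out$fp
  out$fn <- n1 - out$tp
  out$fpr <- out$fp / n0
  out$tpr <- out$tp / n1
  structure(out, class = c("roc_curve", class(out)))
}

#' Trapezoidal area under a ROC curve
#'
#' @param roc A [roc_curve()].
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(roc) {
  n <- nrow(roc)
  sum(diff(roc$fpr) * (roc$tpr[-1] + roc$tpr[-n]) / 2)
}

#' Optimal decision point
#'
#' The threshold with the fewest cumulative false positives plus false
#' negatives; ties are broken toward the higher threshold.
#'
#' @param roc A [roc_curve()].
#' @return List with `threshold`, `fp`, `fn` and `cost` (= fp + fn).
#' @export
optimal_threshold <- function(roc) {
  cost <- roc$fp + roc$fn
  i <- which.min(cost)  # thresholds descending -> first minimum is highest
  list(threshold = roc$threshold[i], fp = roc$fp[i], fn = roc$fn[i],
       cost = cost[i])
}

#' One-vs-rest multiclass AUC
#'
#' Computes a ROC AUC per class, treating that class as positive and all
#' others as one generic negative class, then averages the sub-AUCs with the
#' given class weights. This makes each class's evaluation independent, so a
#' class may be *substituted*: its AUC computed from an alternate fold's
#' scores and labels (e.g. the testing fold when the class has no evaluation
#' instances) without affecting any other class. Down-weighting a class
#' (weight suppression) likewise only shifts the weighted mean.
#'
#' @param scores Numeric matrix (or data frame) of per-frame class scores,
#'   one column per class.
#' @param labels Character vector of true classes, aligned with rows.
#' @param classes Class vector; defaults to `colnames(scores)`.
#' @param weights Nonnegative per-class weights (named or in class order);
#'   default uniform. Scaling all weights by a constant leaves the average
#'   unchanged.
#' @param substitutions Named list, class -> `list(scores=, labels=)` with the
#'   alternate fold's score matrix (or positive-class score vector) and true
#'   labels.
#' @return List with `average`, and `per_class` (tibble `class, auc, weight,
#'   source, included`). Classes with no positives or no negatives in both
#'   primary and substitute data are excluded with a warning.
#' @export
ovr_auc <- function(scores, labels, classes = NULL, weights = NULL,
                    substitutions = list()) {
  scores <- as.matrix(scores)
  classes <- classes %||% colnames(scores)
  stopifnot(!is.null(classes), nrow(scores) == length(labels))
  weights <- weights %||% setNames(rep(1, length(classes)), classes)
  if (is.null(names(weights))) names(weights) <- classes
  stopifnot(all(weights >= 0), any(weights > 0))

  one <- function(cl) {
    sub <- substitutions[[cl]]
    if (!is.null(sub)) {
      s <- sub$scores
      if (is.matrix(s) || is.data.frame(s)) s <- as.matrix(s)[, cl]
      pos <- sub$labels == cl
      src <- "substitute"
    } else {
      s <- scores[, cl]
      pos <- labels == cl
      src <- "primary"
    }
    if (!any(pos) || all(pos)) {
      return(list(auc = NA_real_, source = src))
    }
    list(auc = auc(roc_curve(s, pos)), source = src)
  }
  res <- lapply(classes, one)
  aucs <- vapply(res, `[[`, numeric(1), "auc")
  src <- vapply(res, `[[`, character(1), "source")
  included <- !is.na(aucs)
  if (any(!included)) {
    warning("class(es) with no positives (or no negatives) in primary and ",
            "substitute data excluded from the average: ",
            paste(classes[!included], collapse = ", "))
  }
  per_class <- tibble(class = classes, auc = aucs,
                      weight = unname(weights[classes]), source = src,
                      included = included)
  avg <- with(per_class[included, ], weighted.mean(auc, weight))
  list(average = avg, per_class = per_class)
}

#' Full metrics report
#'
#' Bundles the confusion matrix, per-class and weighted metrics, accuracy and
#' (when scores are supplied) the one-vs-rest AUC analysis into a single
#' report object with a Markdown renderer shaped like the published summary
#' tables (ratios at 2 decimals, percentages at 1).
#'
#' @param cm A [confusion_matrix()].
#' @param scores,labels Optional per-frame class scores and true labels for
#'   the AUC analysis.
#' @param weights,substitutions Passed to [ovr_auc()].
#' @return A list of class `metrics_report`.
#' @export
metrics_report <- function(cm, scores = NULL, labels = NULL,
                           weights = NULL, substitutions = list()) {
  rep <- list(confusion = cm,
              per_class = per_class_metrics(cm),
              weighted = weighted_metrics(cm))
  if (!is.null(scores)) {
    rep$auc <- ovr_auc(scores, labels, classes = rownames(cm),
                       weights = weights, substitutions = substitutions)
  }
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(format_markdown(x), sep = "\n")
  invisible(x)
}

#' Render a metrics report as Markdown
#'
#' @param report A [metrics_report()].
#' @return Character vector of Markdown lines.
#' @export
format_markdown <- function(report) {
  cm <- report$confusion
  classes <- rownames(cm)
  pc <- report$per_class
  lines <- c(
    paste0("| Label\\Predicted | ", paste(classes, collapse = " | "),
           " | Precision | Recall | F1 |"),
    paste0("|", paste(rep("---|", length(classes) + 4), collapse = ""))
  )
  for (i in seq_along(classes)) {
    lines <- c(lines, sprintf(
      "| %s | %s | %.2f | %.2f | %.2f |", classes[i],
      paste(format(cm[i, ], big.mark = ","), collapse = " | "),
      pc$precision[i], pc$recall[i], pc$f1[i]))
  }
  w <- report$weighted
  lines <- c(lines, "",
             sprintf("Weighted precision %.2f, recall %.2f, F1 %.2f; accuracy %.1f%%.",
                     w$precision, w$recall, w$f1, 100 * w$accuracy))
  if (!is.null(report$auc)) {
    subbed <- report$auc$per_class$class[
      report$auc$per_class$source == "substitute"]
    lines <- c(lines, sprintf("Averaged one-vs-rest AUC %.1f.",
                              100 * report$auc$average))
    if (length(subbed)) {
      lines <- c(lines, paste0("Substituted class(es): ",
                               paste(subbed, collapse = ", "), "."))
    }
  }
  lines
}

#' Write a metrics report as JSON (full precision)
#'
#' @param report A [metrics_report()].
#' @param path Output path.
#' @export
write_metrics_report <- function(report, path) {
  out <- list(
    confusion = list(classes = rownames(report$confusion),
                     counts = unclass(report$confusion)),
    per_class = report$per_class,
    weighted = report$weighted
  )
  if (!is.null(report$auc)) {
    out$auc <- list(average = report$auc$average,
                    per_class = report$auc$per_class)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read per-frame predictions from CSV
#'
#' Layout: `video_id, second_index, true`, one score column per class.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_predictions <- function(path) {
  as_tibble(read.csv(path, check.names = FALSE, stringsAsFactors = FALSE))
}
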