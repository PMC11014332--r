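# Leakage-aware fold assignment: whole videos are placed into training /
# testing / evaluation folds so that each fold's class distribution matches
# the pooled distribution, scored by weighted chi-square distance. Assigning
# whole videos (never frames) prevents visually near-identical neighboring
# frames from leaking between training and evaluation.

FOLDS <- c("training", "testing", "evaluation")

#' Fold targets and constraints
#'
#' @param fractions Target fold shares by frame count; must sum to 1. Names
#'   define the folds (default training/testing/evaluation at 80/10/10).
#' @param weights Per-fold weights for the weighted chi-square score; default
#'   equal to `fractions` (larger folds matter more to downstream training).
#' @param tolerance Allowed absolute deviation of each fold's frame share from
#'   its target (fraction of total frames).
#' @return A list of class `fold_targets`.
#' @export
fold_targets <- function(fractions = c(training = 0.8, testing = 0.1,
                                       evaluation = 0.1),
                         weights = NULL, tolerance = 0.05) {
  stopifnot(abs(sum(fractions) - 1) < 1e-8, all(fractions > 0),
            !is.null(names(fractions)))
  weights <- weights %||% fractions
  stopifnot(identical(names(weights), names(fractions)))
  structure(list(fractions = fractions, weights = weights,
                 tolerance = tolerance, folds = names(fractions)),
            class = "fold_targets")
}

#' Per-video class profiles
#'
#' Summarizes labeled per-second records (one frame per labeled second) into
#' one class-count row per video, the unit over which folds are assigned.
#'
#' @param seconds Labeled records from [label_seconds()].
#' @param tax The [taxonomy_map()] whose label column is profiled.
#' @param label_col Column holding the class labels; default derived from the
#'   taxonomy name (`t1`, `t2`, `t3`).
#' @return A list of class `video_profiles`: `counts` (videos x classes
#'   integer matrix), `classes`, `n_frames`.
#' @export
video_profiles <- function(seconds, tax, label_col = NULL) {
  label_col <- label_col %||% tolower(strsplit(tax$name, "_")[[1]][1])
  vids <- sort(unique(seconds$video_id))
  counts <- t(vapply(vids, function(v) {
    class_distribution(seconds[[label_col]][seconds$video_id == v],
                       tax)$counts
  }, integer(length(tax$classes))))
  rownames(counts) <- vids
  as_video_profiles(counts)
}

#' @rdname video_profiles
#' @param counts Integer matrix of class counts with video ids as row names.
#' @export
as_video_profiles <- function(counts) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)), all(counts >= 0))
  structure(list(counts = counts, classes = colnames(counts),
                 n_frames = rowSums(counts)),
            class = "video_profiles")
}

#' Read/write per-video class profiles as wide CSV
#'
#' Layout: `video_id` plus one column per class.
#' @param path File path.
#' @export
read_video_profiles <- function(path) {
  d <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(d[, setdiff(names(d), "video_id"), drop = FALSE])
  rownames(m) <- d$video_id
  storage.mode(m) <- "integer"
  as_video_profiles(m)
}

#' @rdname read_video_profiles
#' @param profiles A `video_profiles` object.
#' @export
write_video_profiles <- function(profiles, path) {
  d <- data.frame(video_id = rownames(profiles$counts),
                  profiles$counts, check.names = FALSE)
  write.csv(d, path, row.names = FALSE)
  invisible(path)
}

fold_count_matrix <- function(mapping, profiles, folds) {
  fc <- matrix(0, nrow = length(folds), ncol = length(profiles$classes),
               dimnames = list(folds, profiles$classes))
  for (f in folds) {
    members <- names(mapping)[mapping == f]
    if (length(members) > 0) {
      fc[f, ] <- colSums(profiles$counts[members, , drop = FALSE])
    }
  }
  fc
}

#' Score a video-fold assignment
#'
#' The weighted chi-square score `sum_f w_f * D(fold_f, pooled)` comparing
#' each fold's class distribution with the pooled distribution of the whole
#' dataset. An assignment with an empty fold (zero frames) is infeasible.
#'
#' @param mapping Named character vector, video id -> fold name.
#' @param profiles [video_profiles()].
#' @param targets [fold_targets()] (supplies fold names and weights).
#' @return List with `score`, `feasible`, `violations` and `fold_counts`.
#' @export
score_assignment <- function(mapping, profiles, targets = fold_targets()) {
  fc <- fold_count_matrix(mapping, profiles, targets$folds)
  empty <- rowSums(fc) == 0
  if (any(empty)) {
    return(list(score = Inf, feasible = FALSE,
                violations = paste0("empty_fold:",
                                    targets$folds[empty]),
                fold_counts = fc))
  }
  pooled <- colSums(profiles$counts)
  score <- sum(vapply(seq_along(targets$folds), function(i) {
    row <- setNames(as.numeric(fc[i, ]), colnames(fc))  # keep names at K = 1
    unname(targets$weights[i]) * chi2_distance(row, pooled)
  }, numeric(1)))
  list(score = score, feasible = TRUE, violations = character(0),
       fold_counts = fc)
}

#' Check assignment constraints
#'
#' Two constraint families: (1) class presence — every class must appear in
#' every fold, but only classes present in at least as many videos as there
#' are folds ("in every fold possible"); a class filmed in fewer videos than
#' folds is exempt. (2) fold size — each fold's frame share must be within
#' `targets$tolerance` of its target fraction.
#'
#' @inheritParams score_assignment
#' @return List with `feasible` and `violations` (character codes
#'   `class_absent:<class>:<fold>` / `fold_share:<fold>` / `empty_fold:<fold>`).
#' @export
check_constraints <- function(mapping, profiles, targets = fold_targets()) {
  fc <- fold_count_matrix(mapping, profiles, targets$folds)
  violations <- character(0)
  empty <- rowSums(fc) == 0
  if (any(empty)) {
    violations <- c(violations, paste0("empty_fold:", targets$folds[empty]))
  }
  # class presence, exempting classes in fewer videos than folds
  n_videos_with <- colSums(profiles$counts > 0)
  constrained <- profiles$classes[n_videos_with >= length(targets$folds)]
  for (cl in constrained) {
    absent <- targets$folds[fc[, cl] == 0]
    violations <- c(violations,
                    if (length(absent)) paste0("class_absent:", cl, ":", absent))
  }
  shares <- rowSums(fc) / sum(profiles$counts)
  off <- abs(shares - targets$fractions) > targets$tolerance + 1e-12
  if (any(off)) {
    violations <- c(violations, paste0("fold_share:", targets$folds[off]))
  }
  list(feasible = length(violations) == 0, violations = violations)
}

evaluate_assignment <- function(mapping, profiles, targets) {
  sc <- score_assignment(mapping, profiles, targets)
  cc <- check_constraints(mapping, profiles, targets)
  violations <- unique(c(sc$violations, cc$violations))
  list(score = sc$score, feasible = length(violations) == 0,
       violations = violations, fold_counts = sc$fold_counts)
}

# lexicographic comparison of fold-index vectors; TRUE if a < b
lex_less <- function(a, b) {
  d <- which(a != b)
  length(d) > 0 && a[d[1]] < b[d[1]]
}

#' Assign videos to folds by minimizing weighted chi-square distance
#'
#' Searches over video-fold assignments for the feasible one whose weighted
#' chi-square score ([score_assignment()]) is minimal, subject to the class
#' presence and fold-size constraints ([check_constraints()]). `exhaustive`
#' mode enumerates all `folds^N` assignments in lexicographic order (so score
#' ties resolve to the lexicographically smallest mapping); `random_search`
#' draws `n_candidates` assignments from a seeded generator with per-video
#' fold probabilities equal to the target fractions and returns the best
#' feasible draw.
#'
#' @param profiles [video_profiles()].
#' @param targets [fold_targets()].
#' @param mode Search mode.
#' @param seed RNG seed for `random_search`.
#' @param n_candidates Number of random draws.
#' @param cap Maximum number of candidates allowed in exhaustive mode.
#' @return A list of class `fold_assignment`: `mapping` (named character),
#'   `fold_distributions`, `score`, `feasible`, `violations`, plus search
#'   metadata.
#' @export
assign_folds <- function(profiles, targets = fold_targets(),
                         mode = c("exhaustive", "random_search"),
                         seed = 1L, n_candidates = 2000L, cap = 3^10) {
  mode <- match.arg(mode)
  vids <- sort(rownames(profiles$counts))
  n <- length(vids)
  if (n < length(targets$folds)) {
    stop("need at least ", length(targets$folds), " videos")
  }
  nf <- length(targets$folds)

  best <- NULL
  best_idx <- NULL
  seen_violations <- character(0)
  consider <- function(idx) {
    mapping <- setNames(targets$folds[idx], vids)
    ev <- evaluate_assignment(mapping, profiles, targets)
    if (!ev$feasible) {
      seen_violations <<- c(seen_violations, ev$violations)
      return(invisible(NULL))
    }
    if (is.null(best) || ev$score < best$score - 1e-12 ||
        (abs(ev$score - best$score) <= 1e-12 && lex_less(idx, best_idx))) {
      best <<- c(ev, list(mapping = mapping))
      best_idx <<- idx
    }
    invisible(NULL)
  }

  if (mode == "exhaustive") {
    total <- nf^n
    if (total > cap) {
      stop("exhaustive mode would enumerate ", total,
           " assignments (cap ", cap, "); use mode = 'random_search'")
    }
    idx <- rep(1L, n)
    for (k in seq_len(total)) {
      consider(idx)
      # odometer increment, last video least significant -> lexicographic order
      j <- n
      while (j >= 1) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= nf) break
        idx[j] <- 1L
        j <- j - 1L
      }
    }
    n_evaluated <- total
  } else {
    set.seed(seed)
    for (k in seq_len(n_candidates)) {
      consider(sample.int(nf, n, replace = TRUE, prob = targets$fractions))
    }
    n_evaluated <- n_candidates
  }

  if (is.null(best)) {
    tab <- sort(table(seen_violations), decreasing = TRUE)
    stop("no feasible assignment found; binding constraints: ",
         paste(sprintf("%s (x%d)", names(tab), tab), collapse = ", "))
  }
  fold_distributions <- lapply(seq_len(nf), function(i) {
    new_class_distribution(setNames(as.integer(best$fold_counts[i, ]),
                                    profiles$classes))
  })
  names(fold_distributions) <- targets$folds
  structure(list(mapping = best$mapping,
                 fold_distributions = fold_distributions,
                 score = best$score, feasible = TRUE,
                 violations = character(0), mode = mode,
                 seed = if (mode == "random_search") seed else NA_integer_,
                 n_evaluated = n_evaluated, targets = targets),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat("<fold_assignment>", x$mode, "over", x$n_evaluated,
      "candidates; score =", signif(x$score, 6), "\n")
  for (f in names(x$fold_distributions)) {
    d <- x$fold_distributions[[f]]
    cat(sprintf("  %-10s %5d frames, %d videos | %s\n", f, d$total,
                sum(x$mapping == f),
                paste(names(d$counts), d$counts, sep = "=", collapse = " ")))
  }
  invisible(x)
}

#' Write a fold assignment to disk
#'
#' Emits an assignment CSV (`video_id, fold`) and a JSON report with the
#' score, per-fold class distributions and constraint status.
#'
#' @param assignment A `fold_assignment`.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @export
write_fold_assignment <- function(assignment, csv_path = NULL,
                                  json_path = NULL) {
  if (!is.null(csv_path)) {
    write.csv(data.frame(video_id = names(assignment$mapping),
                         fold = unname(assignment$mapping)),
              csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    rep <- list(score = assignment$score, feasible = assignment$feasible,
                violations = assignment$violations, mode = assignment$mode,
                fold_distributions = lapply(assignment$fold_distributions,
                                            function(d) as.list(d$counts)))
    jsonlite::write_json(rep, json_path, auto_unbox = TRUE, pretty = TRUE)
  }
  invisible(assignment)
}
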