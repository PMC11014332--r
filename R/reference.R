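# Bundled reference data: the evaluation-phase confusion matrices published
# by a direct-observation annotation study of free-living adults (one matrix
# per taxonomy), re-entered as plain-text count fixtures, together with the
# per-class precision/recall/F1 and overall accuracies printed alongside
# them. They serve as a regression target for the evaluation harness: the
# metrics recomputed from the counts must reproduce every printed value.

#' Bundled reference confusion matrices
#'
#' Loads the three published evaluation-phase confusion matrices (frame
#' counts; rows = hand-annotated truth, columns = model predictions), one per
#' taxonomy. The activity-type matrix's `running` row comes from the testing
#' fold (the class appeared in only two videos, so no evaluation-fold
#' assignment was possible), which is why its counts dominate that matrix.
#'
#' @return Named list of [confusion_matrix()] objects
#'   (`T1_sedentary`, `T2_activity_type`, `T3_intensity`).
#' @export
reference_confusion_matrices <- function() {
  files <- c(T1_sedentary = "confusion_t1_sedentary.csv",
             T2_activity_type = "confusion_t2_activity_type.csv",
             T3_intensity = "confusion_t3_intensity.csv")
  lapply(files, function(f) {
    p <- system.file("extdata", f, package = "vidobs", mustWork = TRUE)
    d <- read.csv(p, check.names = FALSE, stringsAsFactors = FALSE)
    m <- as.matrix(d[, -1, drop = FALSE])
    rownames(m) <- d$class
    storage.mode(m) <- "integer"
    as_confusion_matrix(m)
  })
}

#' Bundled reference metric values
#'
#' The per-class precision/recall/F1 (2 decimals) and overall accuracies
#' (percent, 1 decimal) printed alongside the reference confusion matrices.
#'
#' @return List with tibbles `per_class` and `accuracy`.
#' @export
reference_metric_values <- function() {
  pc <- system.file("extdata", "reference_metrics.csv", package = "vidobs",
                    mustWork = TRUE)
  acc <- system.file("extdata", "reference_accuracy.csv", package = "vidobs",
                     mustWork = TRUE)
  list(per_class = as_tibble(read.csv(pc, stringsAsFactors = FALSE)),
       accuracy = as_tibble(read.csv(acc, stringsAsFactors = FALSE)))
}

#' Recompute and verify the reference tables
#'
#' Recomputes per-class precision/recall/F1 and overall accuracy from the
#' bundled count matrices with [per_class_metrics()] / [weighted_metrics()]
#' and compares them, at the printed rounding (2 decimals for ratios, 0.1
#' percentage point for accuracies), with the printed values.
#'
#' @return List with `per_class` (tibble incl. `match` column), `accuracy`
#'   (tibble incl. `match`), and `all_match`.
#' @export
verify_reference_tables <- function() {
  cms <- reference_confusion_matrices()
  ref <- reference_metric_values()
  rows <- lapply(names(cms), function(tx) {
    pc <- per_class_metrics(cms[[tx]])
    tibble(taxonomy = tx, class = pc$class,
           precision = round(pc$precision, 2),
           recall = round(pc$recall, 2),
           f1 = round(pc$f1, 2))
  })
  got <- do.call(rbind, rows)
  want <- ref$per_class
  key <- function(d) paste(d$taxonomy, d$class)
  want <- want[match(key(got), key(want)), ]
  got$match <- got$precision == want$precision &
    got$recall == want$recall & got$f1 == want$f1
  accs <- tibble(
    taxonomy = names(cms),
    accuracy_pct = unname(vapply(cms, function(m) {
      100 * weighted_metrics(m)$accuracy
    }, numeric(1)))
  )
  accs$reference_pct <- ref$accuracy$accuracy_pct[
    match(accs$taxonomy, ref$accuracy$taxonomy)]
  accs$match <- abs(accs$accuracy_pct - accs$reference_pct) <= 0.05
  list(per_class = got, accuracy = accs,
       all_match = all(got$match) && all(accs$match))
}
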