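test_that("confusion matrices tally truth rows against prediction columns", {
  classes <- c("a", "b", "c")
  cm <- confusion_matrix(c("a", "b", "c", "a"), c("a", "b", "c", "a"), classes)
  expect_equal(unname(diag(cm)), c(2L, 1L, 1L))
  expect_equal(sum(cm) - sum(diag(cm)), 0L)
  expect_error(confusion_matrix("d", "a", classes), "outside")
  # a never-predicted class keeps its empty column
  cm2 <- confusion_matrix(c("a", "b"), c("a", "a"), classes)
  expect_equal(unname(colSums(cm2)), c(2L, 0L, 0L))
})

test_that("re-tallying an expanded label stream recovers the bundled matrix", {
  cm <- reference_confusion_matrices()$T1_sedentary
  truth <- rep(rep(rownames(cm), each = ncol(cm)), as.vector(t(cm)))
  pred <- rep(rep(colnames(cm), nrow(cm)), as.vector(t(cm)))
  again <- confusion_matrix(truth, pred, rownames(cm))
  expect_equal(unclass(again), unclass(cm))
  # conservation: trace + off-diagonal = number of frames
  expect_equal(sum(diag(again)) + (sum(again) - sum(diag(again))),
               length(truth))
})

test_that("per-class metrics follow the precision/recall/F1 formulas", {
  cm <- as_confusion_matrix(matrix(c(8L, 2L, 1L, 9L), 2, byrow = TRUE,
                                   dimnames = list(c("p", "n"), c("p", "n"))))
  pc <- per_class_metrics(cm)
  expect_equal(pc$precision[1], 8 / 9)
  expect_equal(pc$recall[1], 8 / 10)
  expect_equal(pc$f1[1], 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8))
  # identity matrix: all metrics 1
  id <- as_confusion_matrix(diag(5L, 3) |>
                              (\(m) {dimnames(m) <- list(letters[1:3],
                                                         letters[1:3]); m})())
  expect_true(all(per_class_metrics(id)[, c("precision", "recall", "f1")] == 1))
  # never-predicted class: precision 0, flagged
  cm0 <- as_confusion_matrix(matrix(c(1L, 0L, 1L, 0L), 2, byrow = TRUE,
                                    dimnames = list(c("x", "y"), c("x", "y"))))
  pc0 <- per_class_metrics(cm0)
  expect_equal(pc0$precision[2], 0)
  expect_true(pc0$never_predicted[2])
})

test_that("weighted metrics are support-weighted and accuracy is the trace", {
  cm <- reference_confusion_matrices()$T1_sedentary
  w <- weighted_metrics(cm)
  expect_equal(w$accuracy, sum(diag(cm)) / sum(cm))
  # support-weighted recall is identically the accuracy
  expect_equal(w$recall, w$accuracy)
  # one-class matrix: everything collapses to the same ratio
  one <- as_confusion_matrix(matrix(7L, 1, 1, dimnames = list("a", "a")))
  w1 <- weighted_metrics(one)
  expect_equal(w1$accuracy, 1)
  expect_equal(w1$precision, w1$recall)
})

test_that("the ROC sweep has proper endpoints and known areas", {
  r <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[nrow(r)], 1)
  expect_equal(r$tpr[nrow(r)], 1)
  expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
  # oracle: 3 of 4 positive-negative pairs correctly ordered
  expect_equal(auc(r), 0.75)
  expect_equal(auc(r), pairwise_auc_oracle(c(0.9, 0.8, 0.4, 0.3),
                                           c(1, 0, 1, 0)))
  # perfect separation and constant scores
  expect_equal(auc(roc_curve(c(3, 2, 1, 0), c(1, 1, 0, 0))), 1.0)
  expect_equal(auc(roc_curve(rep(0.5, 6), c(1, 0, 1, 0, 1, 0))), 0.5)
  expect_error(roc_curve(1:3, c(1, 1, 1)), "positive and one negative")
})

test_that("trapezoidal AUC equals the pair-counting statistic", {
  set.seed(21)
  for (i in 1:50) {
    n <- sample(20:400, 1)
    s <- round(runif(n), sample(1:3, 1))  # coarse grids force ties
    l <- runif(n) < 0.4
    if (!any(l) || all(l)) next
    expect_equal(auc(roc_curve(s, l)), pairwise_auc_oracle(s, l))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  s <- runif(300)
  l <- runif(300) < 0.5
  expect_equal(auc(roc_curve(s, l)),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE))))
})

test_that("the optimal decision point minimizes FP + FN", {
  # perfect separation: zero cost attainable
  r <- roc_curve(c(3, 2, 1, 0), c(1, 1, 0, 0))
  expect_equal(optimal_threshold(r)$cost, 0)
  # all-identical scores: best is min(#pos, #neg)
  r2 <- roc_curve(rep(0.7, 10), rep(c(1, 0), c(3, 7)))
  expect_equal(optimal_threshold(r2)$cost, 3)
  # the 4-point example: minimal cost 1, ties to the higher threshold
  r3 <- roc_curve(c(0.9, 0.8, 0.4, 0.3), c(1, 0, 1, 0))
  opt <- optimal_threshold(r3)
  expect_equal(opt$cost, 1)
  costs <- r3$fp + r3$fn
  expect_equal(opt$threshold, max(r3$threshold[costs == 1]))
})

test_that("one-vs-rest AUC averages, weights and substitutes per class", {
  set.seed(13)
  n <- 200
  lab <- sample(c("a", "b"), n, replace = TRUE)
  sa <- ifelse(lab == "a", 0.8, 0.2) + rnorm(n, sd = 0.3)
  scores <- cbind(a = sa, b = -sa)
  o <- ovr_auc(scores, lab)
  # symmetric two-class scores: both sub-AUCs equal, average equals either
  expect_equal(o$per_class$auc[1], o$per_class$auc[2])
  expect_equal(o$average, o$per_class$auc[1])

  # weight scaling invariance and 94% suppression as a weighted mean
  lab3 <- sample(c("a", "b", "c"), n, replace = TRUE)
  sc3 <- matrix(runif(3 * n), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  diag_boost <- cbind(lab3 == "a", lab3 == "b", lab3 == "c") * 0.3
  sc3 <- sc3 + diag_boost
  base <- ovr_auc(sc3, lab3)
  scaled <- ovr_auc(sc3, lab3, weights = c(a = 3, b = 3, c = 3))
  expect_equal(base$average, scaled$average)
  supp <- ovr_auc(sc3, lab3, weights = c(a = 1, b = 1, c = 0.06))
  pc <- base$per_class$auc
  expect_equal(supp$average, sum(pc * c(1, 1, 0.06)) / 2.06)

  # substitution affects only its class
  alt_lab <- sample(c("a", "b", "c"), 100, replace = TRUE)
  alt_sc <- matrix(runif(300), ncol = 3,
                   dimnames = list(NULL, c("a", "b", "c")))
  sub <- ovr_auc(sc3, lab3,
                 substitutions = list(c = list(scores = alt_sc,
                                               labels = alt_lab)))
  expect_equal(sub$per_class$auc[1:2], base$per_class$auc[1:2])
  expect_equal(sub$per_class$auc[3],
               auc(roc_curve(alt_sc[, "c"], alt_lab == "c")))
  expect_equal(sub$per_class$source, c("primary", "primary", "substitute"))

  # a class with no instances anywhere is excluded with a warning
  lab_no_c <- sample(c("a", "b"), n, replace = TRUE)
  expect_warning(o2 <- ovr_auc(sc3, lab_no_c), "excluded")
  expect_false(o2$per_class$included[3])
})

test_that("reports render rounded Markdown and full-precision JSON", {
  cm <- reference_confusion_matrices()$T1_sedentary
  rep <- metrics_report(cm)
  md <- format_markdown(rep)
  expect_true(any(grepl("\\| sedentary \\|", md)))
  expect_true(any(grepl("accuracy 87.4%", md)))
  p <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(rep, p)
  j <- jsonlite::read_json(p)
  expect_equal(j$weighted$accuracy, sum(diag(cm)) / sum(cm), tolerance = 1e-12)
})
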