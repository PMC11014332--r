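dist_of <- function(...) {
  counts <- c(...)
  vidobs:::new_class_distribution(counts)
}

test_that("chi-square distance has its closed-form values and symmetry", {
  p <- dist_of(A = 3L, B = 7L)
  expect_equal(chi2_distance(p, p), 0)
  # disjoint one-hot distributions: 1/2 * (1 + 1) = 1
  expect_equal(chi2_distance(dist_of(A = 5L, B = 0L), dist_of(A = 0L, B = 9L)),
               1.0)
  set.seed(11)
  for (i in 1:1000) {
    a <- setNames(rexp(3), c("x", "y", "z"))
    b <- setNames(rexp(3), c("x", "y", "z"))
    expect_equal(chi2_distance(a, b), chi2_distance(b, a))
    expect_gte(chi2_distance(a, b), 0)
  }
  expect_error(chi2_distance(dist_of(A = 0L, B = 0L), p), "zero total")
})

test_that("the Pearson goodness-of-fit variant matches its formula", {
  p <- c(A = 0.5, B = 0.5)
  q <- c(A = 0.25, B = 0.75)
  expect_equal(chi2_distance(p, q, method = "pearson"),
               0.25^2 / 0.25 + 0.25^2 / 0.75)
})

toy_profiles <- function() {
  as_video_profiles(matrix(
    c(40L, 40L, 5L, 5L,
      10L, 30L, 5L, 45L), ncol = 2,
    dimnames = list(c("v1", "v2", "v3", "v4"), c("A", "B"))))
}

test_that("assignment scores rank class balance and collapse with weights", {
  prof <- toy_profiles()
  targets <- fold_targets(c(training = 0.5, testing = 0.25, evaluation = 0.25),
                          tolerance = 1)
  # hand-evaluated candidates: spreading the A-heavy and B-heavy videos
  even <- setNames(c("training", "training", "testing", "evaluation"),
                   c("v1", "v2", "v3", "v4"))
  skew <- setNames(c("training", "testing", "training", "evaluation"),
                   c("v1", "v2", "v3", "v4"))
  s_even <- score_assignment(even, prof, targets)$score
  s_skew <- score_assignment(skew, prof, targets)$score
  expect_lt(s_even, s_skew)

  # every fold matching pooled proportions scores zero
  prof2 <- as_video_profiles(matrix(
    rep(c(6L, 4L), 3), ncol = 2, byrow = TRUE,
    dimnames = list(c("v1", "v2", "v3"), c("A", "B"))))
  m <- setNames(c("training", "testing", "evaluation"), c("v1", "v2", "v3"))
  t3 <- fold_targets(c(training = 1/3, testing = 1/3, evaluation = 1/3),
                     tolerance = 1)
  expect_equal(score_assignment(m, prof2, t3)$score, 0)

  # weight collapse: (1, 0, 0) scores the training fold alone
  t_only <- fold_targets(weights = c(training = 1, testing = 0,
                                     evaluation = 0))
  s <- score_assignment(even, prof, t_only)$score
  pooled <- colSums(prof$counts)
  train_counts <- colSums(prof$counts[c("v1", "v2"), ])
  expect_equal(s, chi2_distance(train_counts, pooled))

  # an empty fold is infeasible
  all_train <- setNames(rep("training", 4), rownames(prof$counts))
  sc <- score_assignment(all_train, prof, targets)
  expect_false(sc$feasible)
  expect_true(any(grepl("empty_fold", sc$violations)))
})

test_that("class-presence constraints exempt classes filmed in < 3 videos", {
  counts <- matrix(
    c(50L, 50L, 50L, 50L, 50L, 50L,
      10L,  8L,  0L,  0L,  0L,  0L),  # rare class in only 2 videos
    ncol = 2, dimnames = list(paste0("v", 1:6), c("common", "rare")))
  prof <- as_video_profiles(counts)
  targets <- fold_targets(tolerance = 1)
  m <- setNames(c("training", "training", "training", "training",
                  "testing", "evaluation"), paste0("v", 1:6))
  cc <- check_constraints(m, prof, targets)
  expect_true(cc$feasible)  # rare absent from testing/evaluation: exempt

  counts5 <- counts
  counts5[3:5, "rare"] <- 5L  # now in 5 videos: constrained
  cc2 <- check_constraints(m, as_video_profiles(counts5), targets)
  expect_false(cc2$feasible)
  expect_true(any(grepl("class_absent:rare:evaluation", cc2$violations)))
})

test_that("fold shares within the tolerance band are feasible", {
  counts <- matrix(c(780L, 110L, 110L), ncol = 1,
                   dimnames = list(paste0("v", 1:3), "A"))
  prof <- as_video_profiles(counts)
  m <- setNames(c("training", "testing", "evaluation"), paste0("v", 1:3))
  cc <- check_constraints(m, prof, fold_targets(tolerance = 0.05))
  expect_true(cc$feasible)  # shares (0.78, 0.11, 0.11)
  cc2 <- check_constraints(m, prof, fold_targets(tolerance = 0.005))
  expect_false(cc2$feasible)
})

test_that("identical videos tie-break to the lexicographically first mapping", {
  counts <- matrix(rep(c(5L, 5L), 3), ncol = 2, byrow = TRUE,
                   dimnames = list(c("v1", "v2", "v3"), c("A", "B")))
  prof <- as_video_profiles(counts)
  targets <- fold_targets(c(training = 1/3, testing = 1/3, evaluation = 1/3),
                          tolerance = 0.01)
  a <- assign_folds(prof, targets)
  expect_equal(a$score, 0)
  # all 6 one-per-fold assignments score 0; lexicographic order of the fold
  # sequence (training < testing < evaluation) selects this one
  expect_equal(unname(a$mapping), c("training", "testing", "evaluation"))
})

test_that("exhaustive search equals the brute-force oracle on the fixture", {
  fx <- make_benchmark_fixture()
  targets <- fold_targets()
  a <- assign_folds(fx$profiles, targets)
  oracle <- brute_force_folds_oracle(fx$profiles$counts, targets$fractions,
                                     targets$weights, targets$tolerance)
  expect_equal(a$score, oracle, tolerance = 1e-12)
  expect_true(a$feasible)
  # fold distributions are the sums of the member profiles
  for (f in names(a$fold_distributions)) {
    members <- names(a$mapping)[a$mapping == f]
    expect_equal(unname(a$fold_distributions[[f]]$counts),
                 unname(colSums(fx$profiles$counts[members, , drop = FALSE])))
  }
})

test_that("random search is seed-deterministic and never beats exhaustive", {
  fx <- make_benchmark_fixture()
  a <- assign_folds(fx$profiles)
  r1 <- assign_folds(fx$profiles, mode = "random_search", seed = 5,
                     n_candidates = 500)
  r2 <- assign_folds(fx$profiles, mode = "random_search", seed = 5,
                     n_candidates = 500)
  expect_identical(r1$mapping, r2$mapping)
  for (s in c(1, 5, 23)) {
    r <- assign_folds(fx$profiles, mode = "random_search", seed = s,
                      n_candidates = 300)
    expect_gte(r$score, a$score - 1e-12)
  }
})

test_that("tightening a constraint never decreases the optimal score", {
  fx <- make_benchmark_fixture()
  loose <- assign_folds(fx$profiles, fold_targets(tolerance = 0.25))
  tight <- assign_folds(fx$profiles, fold_targets(tolerance = 0.05))
  expect_lte(loose$score, tight$score + 1e-12)
})

test_that("infeasible problems report their binding constraints", {
  counts <- matrix(c(10L, 10L, 10L), ncol = 1,
                   dimnames = list(paste0("v", 1:3), "A"))
  prof <- as_video_profiles(counts)
  # every video is 1/3 of frames: 80/10/10 within 0.01 is impossible
  expect_error(assign_folds(prof, fold_targets(tolerance = 0.01)),
               "binding constraints.*fold_share")
})

test_that("profiles round-trip through the wide CSV layout", {
  fx <- make_benchmark_fixture()
  p <- withr::local_tempfile(fileext = ".csv")
  write_video_profiles(fx$profiles, p)
  back <- read_video_profiles(p)
  expect_equal(back$counts, fx$profiles$counts)
})
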