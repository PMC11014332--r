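test_that("the bbox extractor places keypoints inside the figure's box", {
  set.seed(12)
  for (cl in c("sedentary", "walking")) {
    fr <- render_frame(cl, size = 64)
    feat <- extract_pose_features(fr)
    expect_true(feat$person_found)
    gray <- apply(fr$pixels, c(1, 2), mean)
    fg <- which(gray > 16, arr.ind = TRUE)
    # geometry oracle: bounding box of the drawn figure, unit coordinates
    xr <- range(fg[, 2] - 1, fg[, 2]) / 64
    yr <- range(fg[, 1] - 1, fg[, 1]) / 64
    xs <- unlist(feat[paste0(keypoint_names(), "_x")])
    ys <- unlist(feat[paste0(keypoint_names(), "_y")])
    expect_true(all(xs >= xr[1] - 1e-9 & xs <= xr[2] + 1e-9))
    expect_true(all(ys >= yr[1] - 1e-9 & ys <= yr[2] + 1e-9))
  }
})

test_that("a blank frame yields person_found FALSE and the zero vector", {
  blank <- image_frame(array(0L, dim = c(32, 32, 3)))
  feat <- extract_pose_features(blank)
  expect_false(feat$person_found)
  expect_true(all(unlist(feat[pose_feature_cols()]) == 0))
})

test_that("feature extraction is deterministic and backends are pluggable", {
  set.seed(8)
  fr <- render_frame("running")
  expect_identical(extract_pose_features(fr), extract_pose_features(fr))
  expect_error(extract_pose_features(fr, backend = "alphapose"),
               "read_pose_features")
  expect_error(extract_pose_features(fr, backend = "nope"), "not registered")
  register_pose_backend("const", function(frame) {
    setNames(c(rep(0.5, 51), 1), c(pose_feature_cols(), "person_found"))
  })
  expect_equal(extract_pose_features(fr, backend = "const")$nose_x, 0.5)
})

separable_data <- function(n_per_video = 60, seed = 4) {
  set.seed(seed)
  vids <- sprintf("v%02d", 1:10)
  rows <- lapply(seq_along(vids), function(i) {
    lab <- rep(c("up", "down"), each = n_per_video / 2)
    feat <- matrix(rnorm(n_per_video * 6, sd = 0.05), ncol = 6)
    feat[lab == "up", 1] <- feat[lab == "up", 1] + 1
    colnames(feat) <- paste0("f", 1:6)
    cbind(tibble::tibble(video_id = vids[i],
                         second_index = seq_len(n_per_video) - 1L,
                         person_found = TRUE),
          as.data.frame(feat), lab = lab)
  })
  d <- do.call(rbind, rows)
  mapping <- setNames(rep(c("training", "testing", "evaluation"),
                          c(8, 1, 1)), vids)
  list(features = tibble::as_tibble(d[, names(d) != "lab"]),
       labels = d$lab, mapping = mapping)
}

test_that("linearly separable classes are learned almost perfectly", {
  d <- separable_data()
  m <- train_classifier(d$features, d$labels, d$mapping, seed = 1)
  te <- d$features$video_id %in% names(d$mapping)[d$mapping == "testing"]
  pr <- predict_frames(m, d$features[te, ])
  expect_gte(mean(pr$predicted == d$labels[te]), 0.99)
  # training frames through their own model
  tr <- d$features$video_id %in% names(d$mapping)[d$mapping == "training"]
  pr_tr <- predict_frames(m, d$features[tr, ])
  expect_gte(mean(pr_tr$predicted == d$labels[tr]), 0.99)
})

test_that("training is reproducible from data, config and seed", {
  d <- separable_data()
  m1 <- train_classifier(d$features, d$labels, d$mapping, seed = 42)
  m2 <- train_classifier(d$features, d$labels, d$mapping, seed = 42)
  expect_equal(m1$best_iteration, m2$best_iteration)
  p1 <- predict_frames(m1, d$features)
  p2 <- predict_frames(m2, d$features)
  expect_equal(p1, p2)
})

test_that("early stopping reverts to the best testing-fold round", {
  d <- separable_data()
  m <- train_classifier(d$features, d$labels, d$mapping, seed = 1)
  log <- m$eval_log[[2]]
  expect_lte(m$best_iteration, m$nrounds)
  expect_true(all(log[m$best_iteration] >= log[seq_along(log) >
                                                 m$best_iteration]))
  # stopped 10 rounds after the best, or ran to the ceiling
  expect_true(m$nrounds == m$best_iteration + 10 ||
                m$nrounds == m$config$nrounds_max)
})

test_that("prediction is row-equivariant and tolerates no-person rows", {
  d <- separable_data()
  m <- train_classifier(d$features, d$labels, d$mapping, seed = 1)
  idx <- sample(nrow(d$features))
  p <- predict_frames(m, d$features)
  p_perm <- predict_frames(m, d$features[idx, ])
  expect_equal(p_perm$predicted, p$predicted[idx])
  # probabilistic scores sum to 1
  expect_true(all(abs(rowSums(as.matrix(p[, m$classes])) - 1) < 1e-6))
  zero <- d$features[1, ]
  zero[, paste0("f", 1:6)] <- 0
  expect_silent(predict_frames(m, zero))
})

test_that("the leakage audit catches evaluation videos in training", {
  d <- separable_data()
  m <- train_classifier(d$features, d$labels, d$mapping, seed = 1)
  expect_true(audit_leakage(m, d$mapping)$ok)
  # flip an assignment after the fact: a training video now marked evaluation
  bad <- d$mapping
  bad[["v01"]] <- "evaluation"
  audit <- audit_leakage(m, bad)
  expect_false(audit$ok)
  expect_equal(audit$offending, "v01")
})

test_that("a class missing from the testing fold triggers a warning", {
  d <- separable_data()
  lab <- d$labels
  te <- d$features$video_id %in% names(d$mapping)[d$mapping == "testing"]
  lab[te] <- "up"  # "down" now absent from testing
  expect_warning(train_classifier(d$features, lab, d$mapping, seed = 1),
                 "absent from testing")
})

test_that("deep classifier backends are explicit adapter stubs", {
  d <- separable_data()
  for (b in c("vit", "cvt", "resnetst")) {
    expect_error(
      train_classifier(d$features, d$labels, d$mapping,
                       config = classifier_config(backend = b), seed = 1),
      "adapter stub")
  }
})

test_that("well-separated Gaussian pose clusters are recovered", {
  fx <- make_benchmark_fixture()
  expect_gte(pose_separation(fx$config), 4)
  a <- assign_folds(fx$profiles)
  key <- paste(fx$features$video_id, fx$features$second_index)
  sk <- paste(fx$seconds$video_id, fx$seconds$second_index)
  labels <- fx$seconds$t2[match(key, sk)]
  m <- suppressWarnings(train_classifier(
    fx$features, labels, a, classes = taxonomy_map("T2_activity_type")$classes,
    seed = 3))
  ev <- fx$features$video_id %in% names(a$mapping)[a$mapping == "evaluation"]
  pr <- predict_frames(m, fx$features[ev, ])
  expect_gte(mean(pr$predicted == labels[ev]), 0.9)
})
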