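# Synthetic multi-video sessions with the statistical structure the pipeline
# assumes: a semi-Markov chain over raw posture codes (exponential dwell
# times rounded to whole seconds), an intensity channel derived from posture
# through a lookup with optional noise (so activity-type and intensity labels
# correlate as in real behavior), class-conditional Gaussian pose features,
# and a stick-figure renderer whose limb geometry depends on the activity
# class. Everything is deterministic under the config seed.

#' Synthetic session configuration
#'
#' Defaults emulate a free-living direct-observation recording: sessions of
#' heterogeneous length dominated by sitting, with bouts of standing, walking
#' and occasional vigorous movement; per-video gamma-distributed mixture
#' weights make the class mixes imbalanced and video-specific.
#'
#' @param n_videos Number of videos.
#' @param duration_range Min/max video duration in seconds.
#' @param codes Raw posture codes used by the simulator.
#' @param dwell_means Named mean dwell time (s) per code; dwells are
#'   exponential (memoryless), rounded to whole seconds, minimum 1 s.
#' @param base_weights Named stationary tendency per code; the transition
#'   matrix sends state `i` to `j != i` with probability proportional to
#'   `base_weights[j]`.
#' @param transition Optional explicit transition matrix over `codes`
#'   (rows sum to 1, zero diagonal); overrides `base_weights`.
#' @param intensity_lookup Named map posture code -> intensity code.
#' @param intensity_noise Probability that a bout's intensity is shifted one
#'   level up or down from the lookup value.
#' @param pose_sd Isotropic standard deviation of the class-conditional pose
#'   clusters (unit-square coordinates).
#' @param pose_missing_prob Probability a frame has no detected person
#'   (all-zero feature vector).
#' @param video_mix_shape Gamma shape of the per-video mixture-weight draw
#'   (smaller = more imbalanced videos).
#' @param video_codes,video_weights,video_durations,video_start Optional
#'   per-video code subsets, weight overrides, fixed durations (s) and forced
#'   initial codes (lists/vectors keyed by video id), for constructing
#'   fixtures.
#' @param seed RNG seed.
#' @return A list of class `session_config`.
#' @export
session_config <- function(n_videos = 6L,
                           duration_range = c(300L, 900L),
                           codes = c("sitting/reclining", "lying down",
                                     "standing", "stand and move", "walk",
                                     "walk with load", "running", "biking"),
                           dwell_means = c("sitting/reclining" = 90,
                                           "lying down" = 120,
                                           "standing" = 25,
                                           "stand and move" = 20,
                                           "walk" = 30,
                                           "walk with load" = 15,
                                           "running" = 20,
                                           "biking" = 40),
                           base_weights = c("sitting/reclining" = 0.45,
                                            "lying down" = 0.05,
                                            "standing" = 0.15,
                                            "stand and move" = 0.08,
                                            "walk" = 0.15,
                                            "walk with load" = 0.04,
                                            "running" = 0.02,
                                            "biking" = 0.06),
                           transition = NULL,
                           intensity_lookup = c("sitting/reclining" = "sedentary",
                                                "lying down" = "sedentary",
                                                "standing" = "light",
                                                "stand and move" = "light",
                                                "walk" = "moderate",
                                                "walk with load" = "moderate",
                                                "running" = "vigorous",
                                                "biking" = "moderate"),
                           intensity_noise = 0.05,
                           pose_sd = 0.02,
                           pose_missing_prob = 0.01,
                           video_mix_shape = 2,
                           video_codes = NULL, video_weights = NULL,
                           video_durations = NULL, video_start = NULL,
                           seed = 1L) {
  stopifnot(all(codes %in% raw_vocabulary("posture")),
            all(codes %in% names(dwell_means)),
            all(codes %in% names(base_weights)),
            all(dwell_means[codes] > 0), all(base_weights[codes] > 0),
            all(intensity_lookup[codes] %in% raw_vocabulary("intensity")))
  if (!is.null(transition)) {
    stopifnot(is.matrix(transition),
              identical(rownames(transition), codes),
              identical(colnames(transition), codes))
    if (any(abs(rowSums(transition) - 1) > 1e-8) || any(transition < 0)) {
      stop("invalid transition matrix: rows must be nonnegative and sum to 1")
    }
  }
  structure(list(n_videos = as.integer(n_videos),
                 duration_range = as.integer(duration_range),
                 codes = codes, dwell_means = dwell_means,
                 base_weights = base_weights, transition = transition,
                 intensity_lookup = intensity_lookup,
                 intensity_noise = intensity_noise, pose_sd = pose_sd,
                 pose_missing_prob = pose_missing_prob,
                 video_mix_shape = video_mix_shape,
                 video_codes = video_codes, video_weights = video_weights,
                 video_durations = video_durations,
                 video_start = video_start,
                 seed = as.integer(seed)),
            class = "session_config")
}

transition_from_weights <- function(codes, w) {
  w <- w[codes]
  m <- matrix(rep(w, each = length(codes)), nrow = length(codes),
              dimnames = list(codes, codes))
  diag(m) <- 0
  m / rowSums(m)
}

# one video's bout sequence: codes and integer dwell lengths summing to d
simulate_bouts <- function(d, codes, weights, trans, dwell_means,
                           start = NULL) {
  state <- start %||% sample(codes, 1, prob = weights[codes])
  out_code <- character(0)
  out_len <- integer(0)
  total <- 0L
  while (total < d) {
    dwell <- max(1L, as.integer(round(rexp(1, 1 / dwell_means[[state]]))))
    dwell <- min(dwell, d - total)
    out_code <- c(out_code, state)
    out_len <- c(out_len, dwell)
    total <- total + dwell
    if (length(codes) > 1) {
      state <- sample(codes, 1, prob = trans[state, codes])
    }
  }
  # merge consecutive identical codes into maximal bouts (an absorbing code
  # yields one event spanning the whole video)
  grp <- cumsum(c(TRUE, out_code[-1] != out_code[-length(out_code)]))
  list(code = out_code[!duplicated(grp)],
       len = as.integer(tapply(out_len, grp, sum)))
}

shift_intensity <- function(intensity, by) {
  levels <- raw_vocabulary("intensity")
  i <- match(intensity, levels) + by
  levels[pmin(length(levels), pmax(1L, i))]
}

#' Generate a synthetic multi-video session
#'
#' Simulates every video of the configured session and returns the event
#' logs (posture and intensity channels, integer-aligned and gap-free), the
#' ground-truth per-second labels with taxonomy columns, and the
#' class-conditional pose-feature table. Ground truth is derived directly
#' from the simulated state sequence, so `rasterize()` on the emitted events
#' must reproduce it exactly — a cross-check the test suite performs.
#'
#' @param config A [session_config()].
#' @return A list of class `synthetic_session` with elements `events`,
#'   `seconds`, `features`, `config`.
#' @export
generate_session <- function(config = session_config()) {
  set.seed(config$seed)
  ids <- sprintf("video_%02d", seq_len(config$n_videos))
  t2 <- taxonomy_map("T2_activity_type")
  means <- pose_class_means()
  events <- list()
  seconds <- list()
  features <- list()
  for (v in ids) {
    d <- as.integer(config$video_durations[[v]] %||%
                      round(runif(1, config$duration_range[1],
                                  config$duration_range[2])))
    codes_v <- config$video_codes[[v]] %||% config$codes
    w_v <- config$video_weights[[v]] %||%
      (config$base_weights[codes_v] *
         rgamma(length(codes_v), shape = config$video_mix_shape))
    names(w_v) <- codes_v
    trans_v <- if (!is.null(config$transition) &&
                   identical(codes_v, config$codes)) {
      config$transition
    } else {
      transition_from_weights(codes_v, w_v)
    }
    bouts <- simulate_bouts(d, codes_v, w_v, trans_v, config$dwell_means,
                            start = config$video_start[[v]])
    end <- cumsum(bouts$len)
    start <- end - bouts$len
    intensity <- unname(config$intensity_lookup[bouts$code])
    flip <- runif(length(intensity)) < config$intensity_noise
    intensity[flip] <- shift_intensity(intensity[flip],
                                       sample(c(-1L, 1L), sum(flip), TRUE))
    events[[v]] <- rbind(
      tibble(video_id = v, channel = "posture", label = bouts$code,
             start_s = as.numeric(start), end_s = as.numeric(end)),
      tibble(video_id = v, channel = "intensity", label = intensity,
             start_s = as.numeric(start), end_s = as.numeric(end))
    )
    sec <- tibble(video_id = v, second_index = 0:(d - 1L),
                  posture = rep(bouts$code, bouts$len),
                  intensity = rep(intensity, bouts$len),
                  is_transition = FALSE)
    seconds[[v]] <- sec
    cls <- apply_taxonomy(sec$posture, t2)
    feat <- means[cls, , drop = FALSE] +
      matrix(rnorm(d * ncol(means), sd = config$pose_sd), nrow = d)
    feat[] <- pmin(1, pmax(0, feat))  # clip in place to keep dimensions
    missing <- runif(d) < config$pose_missing_prob
    feat[missing, ] <- 0
    ftab <- tibble(video_id = v, second_index = sec$second_index,
                   person_found = !missing)
    features[[v]] <- cbind(ftab, as.data.frame(feat))
  }
  seconds <- label_seconds(do.call(rbind, seconds))
  structure(list(events = do.call(rbind, events), seconds = seconds,
                 features = as_tibble(do.call(rbind, features)),
                 config = config),
            class = "synthetic_session")
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat("<synthetic_session>", length(unique(x$seconds$video_id)), "videos,",
      nrow(x$seconds), "labeled seconds\n")
  invisible(x)
}

# per-class figure geometry: keypoint layout (unit square, y down) plus the
# figure's height/width fractions of the canvas; sedentary figures are
# compact and wide, locomotion figures tall with split legs
class_geometry <- function(label) {
  t2 <- taxonomy_map("T2_activity_type")
  if (!label %in% t2$classes) {
    stop("unknown activity-type class: ", label)
  }
  lay <- kp_layout()
  clamp <- function(m) {
    m[] <- pmin(0.98, pmax(0.02, m))  # keep dim: pmin(scalar, .) drops it
    m
  }
  switch(label,
    sedentary = {
      lay[, "y"] <- 0.25 + 0.5 * lay[, "y"]
      lay[, "x"] <- 0.5 + (lay[, "x"] - 0.5) * 1.3
      list(layout = clamp(lay), h_frac = 0.45, w_frac = 0.60)
    },
    mixed_movement = {
      arms <- c("left_elbow", "right_elbow")
      wrists <- c("left_wrist", "right_wrist")
      lay[arms, "y"] <- lay[arms, "y"] - 0.2
      lay[wrists, "y"] <- lay[wrists, "y"] - 0.3
      list(layout = clamp(lay), h_frac = 0.75, w_frac = 0.55)
    },
    walking = {
      lay[c("left_ankle", "left_knee"), "x"] <-
        lay[c("left_ankle", "left_knee"), "x"] - c(0.12, 0.06)
      lay[c("right_ankle", "right_knee"), "x"] <-
        lay[c("right_ankle", "right_knee"), "x"] + c(0.12, 0.06)
      lay[c("left_wrist", "right_wrist"), "x"] <-
        lay[c("left_wrist", "right_wrist"), "x"] + c(0.08, -0.08)
      list(layout = clamp(lay), h_frac = 0.85, w_frac = 0.45)
    },
    running = {
      lay[c("left_ankle", "left_knee"), "x"] <-
        lay[c("left_ankle", "left_knee"), "x"] - c(0.2, 0.1)
      lay[c("right_ankle", "right_knee"), "x"] <-
        lay[c("right_ankle", "right_knee"), "x"] + c(0.2, 0.1)
      lay[, "x"] <- lay[, "x"] + 0.08 * (1 - lay[, "y"])
      lay[c("left_wrist", "right_wrist"), "y"] <-
        lay[c("left_wrist", "right_wrist"), "y"] - 0.15
      list(layout = clamp(lay), h_frac = 0.80, w_frac = 0.55)
    })
}

#' Class-conditional pose-feature means
#'
#' One mean feature vector per activity-type class, derived from the class
#' figure geometry ([class_geometry()]); confidence coordinates have mean
#' 0.9. With the default cluster spread these means are far apart relative
#' to `pose_sd` (see [pose_separation()]).
#'
#' @return Matrix, classes x `3K` features.
#' @export
pose_class_means <- function() {
  t2 <- taxonomy_map("T2_activity_type")
  m <- t(vapply(t2$classes, function(cl) {
    g <- class_geometry(cl)
    x <- 0.5 + (g$layout[, "x"] - 0.5) * g$w_frac
    y <- 0.1 + g$layout[, "y"] * g$h_frac
    as.vector(rbind(x, y, rep(0.9, nrow(g$layout))))
  }, numeric(3 * 17)))
  colnames(m) <- pose_feature_cols(17L)
  m
}

#' Separation of the pose clusters in sigma units
#'
#' Minimum pairwise Euclidean distance between class mean vectors divided by
#' the isotropic cluster standard deviation.
#'
#' @param config A [session_config()].
#' @return Scalar separation (unitless, in multiples of `pose_sd`).
#' @export
pose_separation <- function(config = session_config()) {
  m <- pose_class_means()
  dmin <- min(stats::dist(m))
  dmin / config$pose_sd
}

draw_segment <- function(canvas, x0, y0, x1, y1, value = 230) {
  n <- max(2L, as.integer(2 * max(abs(x1 - x0), abs(y1 - y0))))
  xs <- pmin(ncol(canvas), pmax(1, round(seq(x0, x1, length.out = n))))
  ys <- pmin(nrow(canvas), pmax(1, round(seq(y0, y1, length.out = n))))
  canvas[cbind(ys, xs)] <- value
  canvas
}

skeleton_edges <- function() {
  rbind(
    c("nose", "left_eye"), c("nose", "right_eye"),
    c("left_eye", "left_ear"), c("right_eye", "right_ear"),
    c("left_shoulder", "right_shoulder"),
    c("left_shoulder", "left_elbow"), c("left_elbow", "left_wrist"),
    c("right_shoulder", "right_elbow"), c("right_elbow", "right_wrist"),
    c("left_shoulder", "left_hip"), c("right_shoulder", "right_hip"),
    c("left_hip", "right_hip"),
    c("left_hip", "left_knee"), c("left_knee", "left_ankle"),
    c("right_hip", "right_knee"), c("right_knee", "right_ankle")
  )
}

#' Render a synthetic stick-figure frame
#'
#' Draws a stick figure on a black canvas whose limb geometry and figure
#' elongation depend on the activity-type class (sedentary figures are
#' compact and low-aspect, walking/running figures tall with split legs),
#' with seeded joint jitter and faint background pixel noise. Used to
#' exercise frame preparation and the pose-extractor interface.
#'
#' @param label An activity-type class
#'   (`sedentary, mixed_movement, walking, running`).
#' @param size Square canvas side in pixels.
#' @param jitter Joint position jitter (fraction of the canvas).
#' @param noise_n Number of faint background noise pixels.
#' @return An [image_frame()].
#' @export
render_frame <- function(label, size = 64L, jitter = 0.02, noise_n = 30L) {
  g <- class_geometry(label)
  # place the figure's bounding box centered on the canvas
  w <- g$w_frac * size
  h <- g$h_frac * size
  x <- (size - w) / 2 + g$layout[, "x"] * w +
    rnorm(nrow(g$layout), sd = jitter * size)
  y <- (size - h) / 2 + g$layout[, "y"] * h +
    rnorm(nrow(g$layout), sd = jitter * size)
  names(x) <- names(y) <- rownames(g$layout)
  canvas <- matrix(0, nrow = size, ncol = size)
  for (i in seq_len(nrow(skeleton_edges()))) {
    e <- skeleton_edges()[i, ]
    canvas <- draw_segment(canvas, x[e[1]], y[e[1]], x[e[2]], y[e[2]])
  }
  # faint sensor noise, below the foreground threshold
  idx <- cbind(sample.int(size, noise_n, TRUE), sample.int(size, noise_n, TRUE))
  canvas[idx] <- pmax(canvas[idx], sample(4:12, noise_n, TRUE))
  px <- array(0L, dim = c(size, size, 3L))
  for (ch in 1:3) px[, , ch] <- as.integer(round(canvas * c(1, 1, 0.9)[ch]))
  image_frame(px, source_video = paste0("synthetic_", label))
}

#' Fixed six-video benchmark fixture
#'
#' A deterministic synthetic bundle for tests and worked examples:
#' heterogeneous video lengths (700/650/600/450/300/300 s, so an 80/10/10
#' frame split is attainable), imbalanced per-video class mixes, and one rare
#' class (`running`) present in exactly two videos — exercising the
#' "every fold possible" exemption in [check_constraints()].
#'
#' @param seed Seed of the frozen construction.
#' @return A `synthetic_session` with an extra element `profiles`
#'   (activity-type [video_profiles()]).
#' @export
make_benchmark_fixture <- function(seed = 20240408L) {
  ids <- sprintf("video_%02d", 1:6)
  durations <- c(700L, 650L, 600L, 450L, 300L, 300L)
  base <- c("sitting/reclining", "lying down", "standing", "stand and move",
            "walk", "biking")
  codes_list <- setNames(rep(list(base), 6), ids)
  codes_list[["video_02"]] <- c(base, "running")
  codes_list[["video_05"]] <- c(base, "running")
  weights_list <- setNames(lapply(1:6, function(i) {
    w <- c("sitting/reclining" = 0.40, "lying down" = 0.05,
           "standing" = 0.15, "stand and move" = 0.10, "walk" = 0.20,
           "biking" = 0.10)
    # tilt each video's mix so class distributions differ across videos
    w[((i - 1) %% length(w)) + 1] <- w[((i - 1) %% length(w)) + 1] * 3
    w
  }), ids)
  weights_list[["video_02"]] <- c(weights_list[["video_02"]],
                                  "running" = 0.30)
  weights_list[["video_05"]] <- c(weights_list[["video_05"]],
                                  "running" = 0.30)
  cfg <- session_config(
    n_videos = 6L, seed = seed,
    video_codes = codes_list,
    video_weights = weights_list,
    video_durations = as.list(setNames(durations, ids)),
    # opening each rare-class video with a running bout guarantees the class
    # appears in exactly those two videos
    video_start = list(video_02 = "running", video_05 = "running"),
    pose_missing_prob = 0
  )
  session <- generate_session(cfg)
  session$profiles <- video_profiles(session$seconds,
                                     taxonomy_map("T2_activity_type"))
  session
}
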