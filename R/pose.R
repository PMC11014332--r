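# Pose-keypoint feature interface. A pluggable backend turns a frame into a
# fixed-length vector of body-landmark triples (x, y, confidence) normalized
# to the unit square — the tabular features the boosted-trees classifier
# consumes. A real skeletal extractor (e.g. a deep keypoint model) is expected
# to run outside this package and hand its output over as a feature CSV; the
# built-in "bbox" backend is a deliberately simple geometric extractor used
# with the synthetic stick-figure renderer.

#' COCO-style keypoint names
#' @param K Number of keypoints (17 for the usual body-landmark set).
#' @return Character vector of keypoint names.
#' @export
keypoint_names <- function(K = 17L) {
  base <- c("nose", "left_eye", "right_eye", "left_ear", "right_ear",
            "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
            "left_wrist", "right_wrist", "left_hip", "right_hip",
            "left_knee", "right_knee", "left_ankle", "right_ankle")
  if (K <= 17L) base[seq_len(K)] else c(base, paste0("kp", 18:K))
}

#' Feature column names for a pose table
#' @inheritParams keypoint_names
#' @return Character vector of length `3K` (`<name>_x`, `_y`, `_c`).
#' @export
pose_feature_cols <- function(K = 17L) {
  as.vector(t(outer(keypoint_names(K), c("x", "y", "c"), paste, sep = "_")))
}

# canonical relative landmark layout inside a standing figure's bounding box
kp_layout <- function() {
  matrix(c(
    0.50, 0.06,  0.45, 0.05,  0.55, 0.05,  0.40, 0.07,  0.60, 0.07,
    0.35, 0.20,  0.65, 0.20,  0.30, 0.35,  0.70, 0.35,  0.28, 0.50,
    0.72, 0.50,  0.40, 0.55,  0.60, 0.55,  0.40, 0.75,  0.60, 0.75,
    0.40, 0.95,  0.60, 0.95
  ), ncol = 2, byrow = TRUE,
  dimnames = list(keypoint_names(17L), c("x", "y")))
}

.pose_backends <- new.env(parent = emptyenv())

#' Register a pose-extractor backend
#'
#' @param name Backend id.
#' @param fn Function `frame -> named numeric vector` of length `3K + 1`
#'   matching [pose_feature_cols()] plus `person_found` (0/1), or a function
#'   that errors (an adapter stub for an external extractor).
#' @export
register_pose_backend <- function(name, fn) {
  assign(name, fn, envir = .pose_backends)
  invisible(name)
}

#' Extract pose-keypoint features from a frame
#'
#' Dispatches to a registered backend. The built-in `"bbox"` backend
#' thresholds the frame, finds the foreground bounding box, and places the
#' 17 canonical landmarks at fixed relative positions inside it (confidence =
#' foreground density); a blank frame yields `person_found = FALSE` and the
#' all-zero vector. The `"alphapose"` id is an adapter stub for an external
#' skeletal extractor: it errors with instructions to supply precomputed
#' feature CSVs via [read_pose_features()].
#'
#' @param frame An [image_frame()].
#' @param backend Backend id (see [register_pose_backend()]).
#' @return One-row tibble with `person_found` and the `3K` feature columns.
#' @export
extract_pose_features <- function(frame, backend = "bbox") {
  if (!exists(backend, envir = .pose_backends)) {
    stop("pose backend '", backend, "' is not registered; ",
         "register one or load precomputed features with read_pose_features()")
  }
  fn <- get(backend, envir = .pose_backends)
  v <- fn(frame)
  out <- as_tibble(as.list(v))
  out$person_found <- as.logical(out$person_found)
  out
}

bbox_backend <- function(frame, threshold = 16) {
  px <- frame$pixels
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3
  fg <- which(gray > threshold, arr.ind = TRUE)
  cols <- pose_feature_cols(17L)
  if (nrow(fg) == 0) {
    return(setNames(c(rep(0, length(cols)), 0), c(cols, "person_found")))
  }
  d <- dim(px)
  r0 <- min(fg[, 1]); r1 <- max(fg[, 1])
  c0 <- min(fg[, 2]); c1 <- max(fg[, 2])
  lay <- kp_layout()
  # landmark positions in unit-square image coordinates (x right, y down)
  x <- (c0 - 1 + lay[, "x"] * (c1 - c0 + 1)) / d[2]
  y <- (r0 - 1 + lay[, "y"] * (r1 - r0 + 1)) / d[1]
  conf <- rep(nrow(fg) / ((r1 - r0 + 1) * (c1 - c0 + 1)), 17)
  setNames(c(rbind(x, y, conf), 1), c(cols, "person_found"))
}

alphapose_stub <- function(frame) {
  stop("the 'alphapose' backend is an adapter for an external skeletal ",
       "extractor and is not bundled; run the extractor separately and load ",
       "its output with read_pose_features()")
}

# deep per-frame classifiers are adapter stubs for the same reason: their
# value is pre-trained weights plus GPU fine-tuning, not desk-scale code
deep_backend_stub <- function(name) {
  function(...) {
    stop("classifier backend '", name, "' is an adapter stub: it requires ",
         "pre-trained weights and GPU fine-tuning outside this package; ",
         "use backend = 'xgboost'")
  }
}

#' Read / write a pose-feature CSV
#'
#' Layout: `video_id, second_index, person_found`, then one column per
#' feature (`nose_x, nose_y, nose_c, ...`). Frames where no person was found
#' carry the all-zero vector.
#'
#' @param path File path.
#' @return For `read_pose_features`, a tibble.
#' @export
read_pose_features <- function(path) {
  d <- as_tibble(read.csv(path, check.names = FALSE,
                          stringsAsFactors = FALSE))
  need <- c("video_id", "second_index", "person_found")
  missing <- setdiff(need, names(d))
  if (length(missing)) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  d$person_found <- as.logical(d$person_found)
  d
}

#' @rdname read_pose_features
#' @param features Pose-feature tibble.
#' @export
write_pose_features <- function(features, path) {
  write.csv(features, path, row.names = FALSE)
  invisible(path)
}

register_pose_backend("bbox", bbox_backend)
register_pose_backend("alphapose", alphapose_stub)
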