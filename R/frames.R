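# Frame preparation: midpoint sampling of representative frames, letterbox
# resize to model resolution with black padding, and training augmentations
# (horizontal flip, lightness jitter in HSL, random crop).

#' Construct an image frame
#'
#' @param pixels H x W x 3 array of integer intensities in `[0, 255]`,
#'   channel order RGB.
#' @param source_video,timestamp_s Provenance metadata.
#' @return A list of class `image_frame`.
#' @export
image_frame <- function(pixels, source_video = NA_character_,
                        timestamp_s = NA_real_) {
  stopifnot(is.array(pixels), length(dim(pixels)) == 3, dim(pixels)[3] == 3,
            dim(pixels)[1] >= 1, dim(pixels)[2] >= 1)
  if (any(pixels < 0 | pixels > 255)) stop("pixel values outside [0, 255]")
  structure(list(pixels = pixels, source_video = source_video,
                 timestamp_s = timestamp_s),
            class = "image_frame")
}

#' @export
print.image_frame <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<image_frame> %dx%dx%d, video=%s, t=%.2fs\n",
              d[1], d[2], d[3], x$source_video, x$timestamp_s))
  invisible(x)
}

#' Frame extraction/resize specification
#'
#' @param target_edge Square output resolution (224 or 384 for the usual
#'   pre-trained input sizes; any positive integer accepted).
#' @param sampling_rate Frames per labeled second.
#' @param pad_value Padding intensity (0 = black).
#' @return A list of class `frame_spec`.
#' @export
frame_spec <- function(target_edge = 224L, sampling_rate = 1L,
                       pad_value = 0L) {
  stopifnot(target_edge >= 1, sampling_rate >= 1, pad_value >= 0,
            pad_value <= 255)
  structure(list(target_edge = as.integer(target_edge),
                 sampling_rate = as.integer(sampling_rate),
                 pad_value = as.integer(pad_value)),
            class = "frame_spec")
}

#' Representative-frame timestamps
#'
#' One timestamp per labeled second at the second's midpoint (maximally
#' distant from boundary transitions); at `sampling_rate = r` each second is
#' subdivided uniformly into `r` midpoints.
#'
#' @param duration_s Number of labeled seconds.
#' @param spec A [frame_spec()].
#' @return Numeric vector of `duration_s * sampling_rate` timestamps.
#' @export
#' @examples
#' sample_timestamps(3, frame_spec())            # 0.5 1.5 2.5
#' sample_timestamps(2, frame_spec(sampling_rate = 2))
sample_timestamps <- function(duration_s, spec = frame_spec()) {
  stopifnot(duration_s >= 1)
  r <- spec$sampling_rate
  secs <- rep(0:(duration_s - 1L), each = r)
  secs + (rep(seq_len(r), duration_s) - 0.5) / r
}

# nearest-neighbour resample of an H x W x 3 array to h2 x w2
nn_resize <- function(pixels, h2, w2) {
  d <- dim(pixels)
  ri <- pmin(d[1], pmax(1L, ceiling((seq_len(h2) - 0.5) * d[1] / h2)))
  ci <- pmin(d[2], pmax(1L, ceiling((seq_len(w2) - 0.5) * d[2] / w2)))
  pixels[ri, ci, , drop = FALSE]
}

#' Letterbox resize with padding
#'
#' Scales the frame so its longest edge equals `target_edge`, preserving the
#' aspect ratio (short edge rounded to the nearest integer, at least 1), then
#' centers the content in a `target_edge` square and fills the excess with
#' `pad_value` pixels (black by default). Handles any orientation and input
#' resolution.
#'
#' @param frame An [image_frame()].
#' @param spec A [frame_spec()].
#' @return A square `image_frame` of side `target_edge`.
#' @export
letterbox_resize <- function(frame, spec = frame_spec()) {
  px <- frame$pixels
  d <- dim(px)
  t <- spec$target_edge
  scale <- t / max(d[1], d[2])
  h2 <- max(1L, as.integer(round(d[1] * scale)))
  w2 <- max(1L, as.integer(round(d[2] * scale)))
  content <- if (h2 == d[1] && w2 == d[2]) px else nn_resize(px, h2, w2)
  out <- array(spec$pad_value, dim = c(t, t, 3L))
  top <- (t - h2) %/% 2L
  left <- (t - w2) %/% 2L
  out[top + seq_len(h2), left + seq_len(w2), ] <- content
  image_frame(out, frame$source_video, frame$timestamp_s)
}

#' Augmentation parameters
#'
#' @param flip_prob Probability of a horizontal flip.
#' @param lightness_prob Probability of applying a lightness jitter.
#' @param lightness_range Multiplicative lightness scale, drawn uniformly
#'   (default +/-10 percent).
#' @param crop_prob Probability of a random crop.
#' @param crop_area_range Retained area fraction of the crop window, drawn
#'   uniformly; the crop is resized back to the input shape.
#' @return A list of class `augment_params`.
#' @export
augment_params <- function(flip_prob = 0.5, lightness_prob = 0.5,
                           lightness_range = c(0.9, 1.1), crop_prob = 0.5,
                           crop_area_range = c(0.8, 1.0)) {
  structure(list(flip_prob = flip_prob, lightness_prob = lightness_prob,
                 lightness_range = lightness_range, crop_prob = crop_prob,
                 crop_area_range = crop_area_range),
            class = "augment_params")
}

# vectorized RGB (0-255 matrices) -> HSL (h in [0,360), s,l in [0,1])
rgb_to_hsl <- function(r, g, b) {
  r <- r / 255; g <- g / 255; b <- b / 255
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  l <- (mx + mn) / 2
  d <- mx - mn
  s <- ifelse(d == 0, 0, d / (1 - abs(2 * l - 1)))
  h <- ifelse(d == 0, 0,
       ifelse(mx == r, ((g - b) / d) %% 6,
       ifelse(mx == g, (b - r) / d + 2, (r - g) / d + 4))) * 60
  list(h = h, s = s, l = l)
}

hsl_to_rgb <- function(h, s, l) {
  c_ <- (1 - abs(2 * l - 1)) * s
  x <- c_ * (1 - abs((h / 60) %% 2 - 1))
  m <- l - c_ / 2
  sector <- floor(h / 60) %% 6
  r <- ifelse(sector == 0 | sector == 5, c_,
       ifelse(sector == 1 | sector == 4, x, 0))
  g <- ifelse(sector == 1 | sector == 2, c_,
       ifelse(sector == 0 | sector == 3, x, 0))
  b <- ifelse(sector == 3 | sector == 4, c_,
       ifelse(sector == 2 | sector == 5, x, 0))
  lapply(list(r = r, g = g, b = b),
         function(v) pmin(255, pmax(0, round((v + m) * 255))))
}

scale_lightness <- function(pixels, factor) {
  hsl <- rgb_to_hsl(pixels[, , 1], pixels[, , 2], pixels[, , 3])
  rgb <- hsl_to_rgb(hsl$h, hsl$s, pmin(1, pmax(0, hsl$l * factor)))
  out <- pixels
  out[, , 1] <- rgb$r; out[, , 2] <- rgb$g; out[, , 3] <- rgb$b
  out
}

#' Randomly augment a training frame
#'
#' Applies, each with its configured probability: a horizontal flip, a
#' lightness jitter (multiplicative scale on the HSL lightness channel,
#' clipped), and a random aspect-preserving crop resized back to the input
#' shape. Draws from R's RNG, so results are deterministic under
#' `set.seed()`; with all probabilities 0 the frame passes through unchanged.
#'
#' @param frame An [image_frame()].
#' @param params An [augment_params()].
#' @return An `image_frame` of the same shape.
#' @export
augment_frame <- function(frame, params = augment_params()) {
  px <- frame$pixels
  d <- dim(px)
  if (runif(1) < params$flip_prob) {
    px <- px[, d[2]:1, , drop = FALSE]
  }
  if (runif(1) < params$lightness_prob) {
    px <- scale_lightness(px, runif(1, params$lightness_range[1],
                                    params$lightness_range[2]))
  }
  if (runif(1) < params$crop_prob) {
    side <- sqrt(runif(1, params$crop_area_range[1],
                       params$crop_area_range[2]))
    ch <- max(1L, as.integer(round(d[1] * side)))
    cw <- max(1L, as.integer(round(d[2] * side)))
    top <- sample.int(d[1] - ch + 1L, 1)
    left <- sample.int(d[2] - cw + 1L, 1)
    px <- nn_resize(px[top:(top + ch - 1L), left:(left + cw - 1L), ,
                       drop = FALSE], d[1], d[2])
  }
  image_frame(px, frame$source_video, frame$timestamp_s)
}

#' Frame manifest linking sampled frames to per-second labels
#'
#' @param seconds Labeled per-second records.
#' @param spec A [frame_spec()].
#' @param dir Directory frames would be written to (paths only; no I/O).
#' @return Tibble `video_id, second_index, timestamp_s, frame_path`.
#' @export
frame_manifest <- function(seconds, spec = frame_spec(), dir = "frames") {
  out <- lapply(unique(seconds$video_id), function(v) {
    idx <- sort(seconds$second_index[seconds$video_id == v])
    r <- spec$sampling_rate
    ts <- rep(idx, each = r) + (rep(seq_len(r), length(idx)) - 0.5) / r
    tibble(video_id = v,
           second_index = rep(idx, each = r),
           timestamp_s = ts,
           frame_path = file.path(dir, v, sprintf("%s_%08.2f.png", v, ts)))
  })
  do.call(rbind, out)
}
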