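# Rasterization of interval annotations to a per-second label stream.
#
# Second grid: 0-based half-open seconds [i, i+1). For each second and channel
# the code covering the strictly largest fraction of the second wins; an exact
# tie goes to the code whose earliest contributing event starts first. A second
# intersected by more than one code on a tracked channel is a transition.

# per-second winners for one channel of one video
rasterize_channel <- function(events, duration_s, tol = 1e-9) {
  label <- rep(UNLABELED, duration_s)
  multi <- rep(FALSE, duration_s)
  if (nrow(events) == 0) {
    return(list(label = label, transition = multi))
  }
  # expand each event into the seconds it touches, with overlap lengths
  pieces <- vector("list", nrow(events))
  for (e in seq_len(nrow(events))) {
    s0 <- max(0L, floor(events$start_s[e]))
    s1 <- min(duration_s - 1L, ceiling(events$end_s[e]) - 1L)
    if (s1 < s0) next
    secs <- s0:s1
    cov <- pmin(events$end_s[e], secs + 1) - pmax(events$start_s[e], secs)
    keep <- cov > tol
    if (!any(keep)) next
    pieces[[e]] <- data.frame(
      second = secs[keep], code = events$label[e], cov = cov[keep],
      start = events$start_s[e], stringsAsFactors = FALSE
    )
  }
  long <- do.call(rbind, pieces)
  if (is.null(long) || nrow(long) == 0) {
    return(list(label = label, transition = multi))
  }
  # aggregate coverage by (second, code); earliest contributing start per code
  agg <- stats::setNames(
    aggregate(long$cov, by = list(second = long$second, code = long$code), sum),
    c("second", "code", "cov"))
  mins <- stats::setNames(
    aggregate(long$start, by = list(second = long$second, code = long$code), min),
    c("second", "code", "start"))
  agg$start <- mins$start[match(paste(agg$second, agg$code, sep = "\r"),
                                paste(mins$second, mins$code, sep = "\r"))]
  # winner per second: max coverage, ties to earliest start, then code order
  ord <- order(agg$second, -agg$cov, agg$start, agg$code)
  agg <- agg[ord, ]
  first <- !duplicated(agg$second)
  win <- agg[first, ]
  # strict-tie handling already covered: ordering puts earliest start first
  label[win$second + 1L] <- win$code
  ncodes <- tabulate(factor(agg$second, levels = 0:(duration_s - 1L)),
                     nbins = duration_s)
  multi <- ncodes > 1L
  list(label = label, transition = multi)
}

#' Rasterize annotation events to second-by-second records
#'
#' Converts the interval events of one video into one record per second on a
#' 0-based half-open second grid. For each tracked channel the code covering
#' the strictly largest fraction of the second is assigned; an exact 50/50 tie
#' goes to the earlier-starting event's code. Seconds intersected by more than
#' one code on either tracked channel are flagged as transitions. Seconds
#' touched by no event get the sentinel `"unlabeled"` (or raise an error in
#' strict mode).
#'
#' @param events Event tibble for a single video (see [parse_events()]).
#' @param duration_s Video duration in whole seconds; defaults to the ceiling
#'   of the last event end.
#' @param strict Error if any second on a tracked channel is uncovered.
#' @return A tibble with columns
#'   `video_id, second_index, posture, intensity, is_transition`.
#' @export
#' @examples
#' ev <- tibble::tibble(
#'   video_id = "v1", channel = "posture",
#'   label = c("sitting/reclining", "walk"),
#'   start_s = c(0, 1.6), end_s = c(1.6, 3))
#' rasterize(ev, duration_s = 3)
rasterize <- function(events, duration_s = NULL, strict = FALSE) {
  vids <- unique(events$video_id)
  if (length(vids) != 1) {
    stop("rasterize() expects events of exactly one video; got ",
         length(vids), " (use rasterize_all() for sessions)")
  }
  if (is.null(duration_s)) duration_s <- as.integer(ceiling(max(events$end_s)))
  duration_s <- as.integer(duration_s)
  if (duration_s < 1) stop("duration_s must be >= 1")

  pos <- rasterize_channel(events[events$channel == "posture", , drop = FALSE],
                           duration_s)
  int <- rasterize_channel(events[events$channel == "intensity", , drop = FALSE],
                           duration_s)
  if (strict && (any(pos$label == UNLABELED) || any(int$label == UNLABELED))) {
    stop("uncovered second(s) in strict mode for video ", vids)
  }
  tibble(
    video_id = vids,
    second_index = 0:(duration_s - 1L),
    posture = pos$label,
    intensity = int$label,
    is_transition = pos$transition | int$transition
  )
}

#' Rasterize a multi-video event table
#'
#' @param events Event tibble covering any number of videos.
#' @param durations Optional named integer vector of durations (seconds) per
#'   video id; defaults to each video's last event end, rounded up.
#' @param strict Passed to [rasterize()].
#' @return Row-bound tibble of per-second records for all videos.
#' @export
rasterize_all <- function(events, durations = NULL, strict = FALSE) {
  vids <- unique(events$video_id)
  out <- lapply(vids, function(v) {
    d <- if (!is.null(durations)) as.integer(durations[[v]]) else NULL
    rasterize(events[events$video_id == v, , drop = FALSE], d, strict = strict)
  })
  do.call(rbind, out)
}

#' Re-aggregate a per-second label stream into intervals
#'
#' Inverse of [rasterize()] for integer-aligned, non-overlapping annotations:
#' maximal runs of identical labels become events. Useful for round-trip
#' checks and for exporting consolidated annotations.
#'
#' @param seconds Per-second records from [rasterize()].
#' @param channel `"posture"` or `"intensity"`.
#' @param drop_unlabeled Drop runs of the `"unlabeled"` sentinel.
#' @return Event tibble on the requested channel.
#' @export
deraster <- function(seconds, channel = c("posture", "intensity"),
                     drop_unlabeled = TRUE) {
  channel <- match.arg(channel)
  out <- lapply(unique(seconds$video_id), function(v) {
    sub <- seconds[seconds$video_id == v, ]
    sub <- sub[order(sub$second_index), ]
    lab <- sub[[channel]]
    r <- rle(lab)
    end <- cumsum(r$lengths)
    start <- end - r$lengths
    tibble(video_id = v, channel = channel, label = r$values,
           start_s = as.numeric(sub$second_index[1] + start),
           end_s = as.numeric(sub$second_index[1] + end))
  })
  out <- do.call(rbind, out)
  if (drop_unlabeled) out <- out[out$label != UNLABELED, , drop = FALSE]
  out
}
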