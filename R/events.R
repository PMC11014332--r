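#' Event-log CSV dialect
#'
#' Describes how the columns of an event-based annotation export map onto the
#' canonical schema `video_id, channel, label, start_s, end_s`. Times are
#' decimal seconds relative to the start of the video. Any annotation tool's
#' export can be converted by renaming columns through a dialect.
#'
#' @param video_id,channel,label,start_s,end_s Column names in the file.
#' @param sep Field separator.
#' @return A list of class `event_dialect`.
#' @export
event_dialect <- function(video_id = "video_id", channel = "channel",
                          label = "label", start_s = "start_s",
                          end_s = "end_s", sep = ",") {
  structure(
    list(video_id = video_id, channel = channel, label = label,
         start_s = start_s, end_s = end_s, sep = sep),
    class = "event_dialect"
  )
}

CHANNELS <- c("posture", "intensity", "domain")

#' Parse an event-based annotation log
#'
#' Reads a CSV export of interval annotations (one row per labeled event on
#' one channel of one video) and validates it. Malformed rows are reported
#' with their file line numbers. Events on the same channel of the same video
#' that overlap by more than `overlap_tol` seconds trigger a warning naming
#' both rows; overlaps are legal input for [rasterize()] (the majority rule
#' resolves them) but usually indicate an annotation error.
#'
#' @param path Path to the CSV file.
#' @param dialect An [event_dialect()] describing the column layout.
#' @param overlap_tol Tolerance in seconds below which touching events are not
#'   considered overlapping.
#' @return A tibble with columns `video_id, channel, label, start_s, end_s`,
#'   sorted by `(video_id, channel, start_s)`.
#' @export
parse_events <- function(path, dialect = event_dialect(), overlap_tol = 1e-6) {
  if (!file.exists(path)) stop("event file not found: ", path)
  raw <- read.csv(path, sep = dialect$sep, check.names = FALSE,
                  stringsAsFactors = FALSE)
  need <- unlist(dialect[c("video_id", "channel", "label", "start_s", "end_s")])
  missing <- setdiff(need, names(raw))
  if (length(missing) > 0) {
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  }
  ev <- tibble(
    video_id = as.character(raw[[dialect$video_id]]),
    channel  = as.character(raw[[dialect$channel]]),
    label    = as.character(raw[[dialect$label]]),
    start_s  = as.numeric(raw[[dialect$start_s]]),
    end_s    = as.numeric(raw[[dialect$end_s]])
  )
  # header occupies line 1, so data row i sits on file line i + 1
  ev$.line <- seq_len(nrow(ev)) + 1L
  validate_events(ev, overlap_tol = overlap_tol)
  ev <- ev[order(ev$video_id, ev$channel, ev$start_s), ]
  ev$.line <- NULL
  ev
}

#' Validate a table of annotation events
#'
#' Checks the invariants of the event schema: nonempty labels, known channels,
#' `start_s >= 0`, `end_s > start_s`. Emits a warning for each same-channel
#' overlap exceeding `overlap_tol`.
#'
#' @param events Data frame with the canonical event columns.
#' @param overlap_tol Overlap tolerance in seconds.
#' @return `events`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_events <- function(events, overlap_tol = 1e-6) {
  line <- events$.line %||% seq_len(nrow(events))
  bad <- function(cond, what) {
    if (any(cond)) {
      stop("validation error: ", what, " in row(s)/line(s): ",
           paste(line[cond], collapse = ", "))
    }
  }
  bad(is.na(events$label) | !nzchar(events$label), "empty label")
  bad(!(events$channel %in% CHANNELS),
      paste0("unknown channel (expected ",
             paste(CHANNELS, collapse = "/"), ")"))
  bad(is.na(events$start_s) | is.na(events$end_s), "non-numeric time")
  bad(events$start_s < 0, "negative start_s")
  bad(events$end_s <= events$start_s, "end_s <= start_s")

  # overlap scan per (video, channel)
  key <- paste(events$video_id, events$channel, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    idx <- idx[order(events$start_s[idx])]
    if (length(idx) < 2) next
    prev <- idx[-length(idx)]
    nxt <- idx[-1]
    over <- events$end_s[prev] - events$start_s[nxt] > overlap_tol
    for (j in which(over)) {
      warning(sprintf(
        "events overlap by %.3f s on video '%s' channel '%s' (rows %s and %s)",
        events$end_s[prev[j]] - events$start_s[nxt[j]],
        events$video_id[idx[1]], events$channel[idx[1]],
        line[prev[j]], line[nxt[j]]), call. = FALSE)
    }
  }
  invisible(events)
}

#' Write events in the canonical CSV dialect
#'
#' @param events Event tibble.
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  write.csv(events[, c("video_id", "channel", "label", "start_s", "end_s")],
            path, row.names = FALSE)
  invisible(path)
}
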