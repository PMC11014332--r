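# Independent oracles used to freeze expected values. Each is deliberately
# naive (brute force / enumeration) and never shares code with the package
# paths it checks.

# AUC as the all-pairs Mann-Whitney statistic: fraction of positive-negative
# pairs ranked correctly, ties counted 1/2
pairwise_auc_oracle <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  cmp <- outer(pos, neg, FUN = function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# per-second coverage of one channel's events, by summing interval overlaps
# with each half-open second
coverage_oracle <- function(events, duration_s) {
  out <- vector("list", duration_s)
  for (i in seq_len(duration_s) - 1L) {
    cov <- numeric(0)
    for (e in seq_len(nrow(events))) {
      o <- min(events$end_s[e], i + 1) - max(events$start_s[e], i)
      if (o > 1e-9) {
        cov[events$label[e]] <- (cov[events$label[e]] %||% 0) + o
      }
    }
    out[[i + 1L]] <- cov
  }
  out
}
`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

# exhaustive fold-assignment oracle: loops over all folds^N assignments with
# its own feasibility and scoring logic expressed directly from definitions
brute_force_folds_oracle <- function(counts, fractions, weights, tolerance) {
  folds <- names(fractions)
  vids <- sort(rownames(counts))
  n <- length(vids)
  pooled <- colSums(counts)
  pooled_p <- pooled / sum(pooled)
  grid <- expand.grid(rep(list(seq_along(folds)), n))
  best <- Inf
  n_videos_with <- colSums(counts > 0)
  for (r in seq_len(nrow(grid))) {
    f <- folds[unlist(grid[r, ])]
    fc <- t(sapply(folds, function(ff) {
      sel <- vids[f == ff]
      if (length(sel) == 0) rep(0, ncol(counts))
      else colSums(counts[sel, , drop = FALSE])
    }))
    colnames(fc) <- colnames(counts)
    tot <- rowSums(fc)
    if (any(tot == 0)) next
    shares <- tot / sum(counts)
    if (any(abs(shares - fractions) > tolerance + 1e-12)) next
    constrained <- colnames(counts)[n_videos_with >= length(folds)]
    if (any(fc[, constrained, drop = FALSE] == 0)) next
    sc <- 0
    for (i in seq_along(folds)) {
      p <- fc[i, ] / tot[i]
      s <- p + pooled_p
      keep <- s > 0
      sc <- sc + unname(weights[i]) * 0.5 *
        sum((p[keep] - pooled_p[keep])^2 / s[keep])
    }
    if (sc < best) best <- sc
  }
  best
}

# random fully-covering integer-grid event set on one channel
random_event_set <- function(duration_s, codes = c("a", "b", "c")) {
  cuts <- sort(sample(seq_len(duration_s * 4 - 1),
                      sample(1:5, 1))) / 4
  bounds <- unique(c(0, cuts, duration_s))
  tibble::tibble(
    video_id = "v", channel = "posture",
    label = sample(codes, length(bounds) - 1, replace = TRUE),
    start_s = bounds[-length(bounds)], end_s = bounds[-1]
  )
}
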