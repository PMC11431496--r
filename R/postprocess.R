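#' Postprocessing configuration
#'
#' Two-step cleanup of detected events: a merging step guaranteeing that
#' two arousal events are separated by at least `merge_gap_s` (5 s — a
#' deliberate relaxation of the 10 s AASM separation to absorb up to 3 s of
#' onset/offset uncertainty), followed by discarding events shorter than
#' `min_duration_s` (3 s, the AASM minimum arousal duration).
#'
#' @param merge_gap_s Minimum allowed gap between events; gaps strictly
#'   smaller are merged.  Must be < 10.
#' @param min_duration_s Minimum event duration; strictly shorter events
#'   are discarded.
#' @return A `postprocess_config` list.
#' @export
postprocess_config <- function(merge_gap_s = 5, min_duration_s = 3) {
  if (merge_gap_s >= 10) stop("merge_gap_s must be < 10 s")
  structure(list(merge_gap_s = merge_gap_s, min_duration_s = min_duration_s),
            class = "postprocess_config")
}

#' Binarize a probability sequence and extract candidate events
#'
#' A second is labeled positive iff its probability is strictly above the
#' threshold; maximal runs of positive seconds become half-open events
#' `[run_start, run_end + 1)`.
#'
#' @param probs Per-second probabilities.
#' @param threshold Decision threshold in (0, 1); ties at the threshold are
#'   negative.
#' @return An `event_list`.
#' @export
binarize_and_extract <- function(probs, threshold) {
  stopifnot(threshold > 0, threshold < 1)
  pos <- probs > threshold
  if (!any(pos)) return(event_list())
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  event_list(starts[keep] - 1, ends[keep])
}

#' Merge events separated by less than the configured gap
#'
#' Consecutive events whose gap is strictly smaller than `merge_gap_s` are
#' fused into one spanning event, transitively; a gap of exactly
#' `merge_gap_s` is preserved.
#'
#' @param events An `event_list`.
#' @param config A [postprocess_config()].
#' @return The merged `event_list`, with attribute `n_merged` counting the
#'   events absorbed into a neighbour.
#' @export
merge_close_events <- function(events, config = postprocess_config()) {
  n <- nrow(events)
  if (n <= 1L) {
    attr(events, "n_merged") <- 0L
    return(events)
  }
  gap <- events$onset[-1L] - events$offset[-n]
  fuse <- gap < config$merge_gap_s
  grp <- cumsum(c(1L, !fuse))
  onset <- tapply(events$onset, grp, min)
  offset <- tapply(events$offset, grp, max)
  out <- event_list(as.numeric(onset), as.numeric(offset))
  attr(out, "n_merged") <- n - nrow(out)
  out
}

#' Discard events shorter than the minimum duration
#'
#' Events strictly shorter than `min_duration_s` are removed; a duration of
#' exactly `min_duration_s` is kept.
#'
#' @param events An `event_list`.
#' @param config A [postprocess_config()].
#' @return The filtered `event_list`, with attribute `n_discarded`.
#' @export
discard_short_events <- function(events, config = postprocess_config()) {
  keep <- event_durations(events) >= config$min_duration_s
  out <- events[keep, , drop = FALSE]
  class(out) <- c("event_list", "data.frame")
  attr(out, "n_discarded") <- sum(!keep)
  out
}

#' Full postprocessing: binarize, merge, then discard
#'
#' The merge step runs before the duration filter, so short detections that
#' sit close together are first fused into one (possibly long enough)
#' event and only then filtered.
#'
#' @param probs Per-second probabilities.
#' @param threshold Decision threshold.
#' @param config A [postprocess_config()].
#' @return An `event_list` with attributes `n_merged` and `n_discarded`
#'   (postprocessing bookkeeping).
#' @export
postprocess <- function(probs, threshold, config = postprocess_config()) {
  raw <- binarize_and_extract(probs, threshold)
  merged <- merge_close_events(raw, config)
  out <- discard_short_events(merged, config)
  attr(out, "n_merged") <- attr(merged, "n_merged")
  out
}

#' Reclassify implausibly long detections as non-arousals
#'
#' Arousals are brief by definition (3-15 s under scoring rules; longer
#' sustained shifts count as awakening).  Detections longer than `max_s`
#' are therefore treated as predicted wakefulness rather than arousal
#' events and removed before event matching.  This also removes the
#' degenerate "one detection spanning the night" solution that would
#' otherwise score a perfect event F1 under the coverage criterion.
#'
#' @param events A detected `event_list`.
#' @param max_s Maximum plausible arousal duration in seconds.
#' @return The filtered `event_list`.
#' @export
discard_long_detections <- function(events, max_s = 30) {
  keep <- event_durations(events) <= max_s
  out <- events[keep, , drop = FALSE]
  class(out) <- c("event_list", "data.frame")
  out
}

# Pooled event-based F1 over validation records at one threshold, with wake
# masking, full postprocessing and the long-detection filter applied.
event_f1_at <- function(threshold, val_probs, val_events, sleep_masks,
                        config, crit, max_detection_s = 30) {
  tp <- fp <- gt_matched <- n_gt <- 0
  for (i in seq_along(val_probs)) {
    det <- discard_long_detections(
      postprocess(val_probs[[i]], threshold, config), max_detection_s)
    gt <- val_events[[i]]
    if (!is.null(sleep_masks)) {
      det <- mask_wake(det, sleep_masks[[i]])
      gt <- mask_wake(gt, sleep_masks[[i]])
    }
    m <- match_events(gt, det, crit)
    tp <- tp + m$tp; fp <- fp + m$fp
    gt_matched <- gt_matched + m$gt_matched; n_gt <- n_gt + m$n_gt
  }
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (n_gt > 0) gt_matched / n_gt else 0
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

#' Optimize the decision threshold for event-based F1
#'
#' The search starts from the pointwise-F1-maximizing threshold `t0` found
#' by a 0.01-step grid sweep, then refines with a three-point pattern: the
#' triple `{t0 - 0.02, t0, t0 + 0.02}` is scored by event-based F1 after
#' full postprocessing; while the best score sits on an endpoint the triple
#' shifts one spacing toward it; when the centre is best the spacing halves
#' to 0.01; the search terminates when the spacing is 0.01 and the centre
#' maximizes event F1 (or at the grid boundary).  Ties prefer the centre,
#' so a flat score surface returns `t0`.
#'
#' @param val_probs List of per-second probability vectors (one per
#'   validation record).
#' @param val_events List of ground-truth `event_list`s.
#' @param sleep_masks Optional list of per-second sleep masks used both for
#'   the pointwise sweep and for wake masking of events.
#' @param config A [postprocess_config()].
#' @param crit A [match_criterion()].
#' @return The selected threshold.
#' @export
optimize_threshold <- function(val_probs, val_events, sleep_masks = NULL,
                               config = postprocess_config(),
                               crit = match_criterion()) {
  # step 1: pointwise-F1 sweep on the 0.01 grid
  probs_all <- unlist(val_probs)
  labels_all <- unlist(lapply(seq_along(val_probs), function(i) {
    lab <- numeric(length(val_probs[[i]]))
    ev <- val_events[[i]]
    for (j in seq_len(nrow(ev))) {
      ts <- floor(ev$onset[j]):(ceiling(ev$offset[j]) - 1)
      ts <- ts[ev$onset[j] < ts + 1 & ev$offset[j] > ts & ts >= 0 &
                 ts < length(lab)]
      lab[ts + 1L] <- 1
    }
    lab
  }))
  if (!is.null(sleep_masks)) {
    keep <- unlist(lapply(seq_along(val_probs), function(i) {
      sleep_masks[[i]][seq_along(val_probs[[i]])] == 1
    }))
    probs_all <- probs_all[keep]
    labels_all <- labels_all[keep]
  }
  grid <- seq(0.01, 0.99, by = 0.01)
  pw_f1 <- vapply(grid, function(th) {
    pred <- probs_all > th
    tp <- sum(pred & labels_all == 1)
    fp <- sum(pred & labels_all == 0)
    fn <- sum(!pred & labels_all == 1)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  t0 <- grid[which.max(pw_f1)]

  # step 2-4: three-point event-F1 pattern search
  cache <- new.env(parent = emptyenv())
  score <- function(th) {
    key <- sprintf("%.4f", th)
    if (is.null(cache[[key]])) {
      cache[[key]] <- event_f1_at(th, val_probs, val_events, sleep_masks,
                                  config, crit)
    }
    cache[[key]]
  }
  clamp <- function(x) min(max(x, 0.01), 0.99)
  spacing <- 0.02
  centre <- t0
  for (iter in seq_len(400L)) {
    lo <- clamp(centre - spacing)
    hi <- clamp(centre + spacing)
    s_lo <- score(lo); s_c <- score(centre); s_hi <- score(hi)
    if (s_c >= s_lo && s_c >= s_hi) {
      if (spacing <= 0.0100001) return(centre)
      spacing <- 0.01
    } else if (s_hi > s_lo || (s_hi == s_lo && s_hi > s_c)) {
      if (hi == centre) return(centre)  # clamped at the boundary
      centre <- hi
    } else {
      if (lo == centre) return(centre)
      centre <- lo
    }
  }
  centre
}
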