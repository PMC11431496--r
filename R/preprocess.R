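#' @title Preprocessing of candidate input channels
#' @name hstarousal-preprocess
#' @description
#' All selected channels are brought to a common 4 Hz resolution and
#' standardized by removing the median and dividing by the interquartile
#' range, computed over the whole record.  No filtering is applied; the only
#' repair is outlier correction on the heart-rate channel (R-peak
#' misdetection artifacts).  Records in which any selected channel is
#' missing or noisy for more than 50% of sleep time are excluded.
NULL

#' Resample a trace to 4 Hz
#'
#' Continuous channels are linearly interpolated onto the 0.25 s grid;
#' binary and categorical channels use nearest-neighbour resampling so no
#' fractional values are introduced.  A 4 Hz input is returned unchanged.
#'
#' @param trace A `signal_trace`.
#' @return A `signal_trace` at 4 Hz of the same duration (within one
#'   sample).
#' @export
resample_to_4hz <- function(trace) {
  if (length(trace$samples) == 0L) stop("cannot resample an empty trace")
  if (trace$rate_hz == 4) return(trace)
  dur <- trace_duration(trace)
  n_out <- max(1L, round(dur * 4))
  t_in <- (seq_along(trace$samples) - 1) / trace$rate_hz
  t_out <- (seq_len(n_out) - 1) / 4
  if (trace$kind == "continuous") {
    y <- stats::approx(t_in, trace$samples, xout = t_out, method = "linear",
                       rule = 2)$y
  } else {
    idx <- pmin(pmax(round(t_out * trace$rate_hz) + 1, 1),
                length(trace$samples))
    y <- trace$samples[idx]
  }
  signal_trace(y, 4, trace$name, trace$kind)
}

#' Robust (median/IQR) standardization of a trace
#'
#' Subtracts the record median and divides by the interquartile range.  A
#' flat trace (IQR = 0) is only median-centred and flagged as degenerate
#' (attribute `degenerate`), so quality assessment can pick it up.
#'
#' @param trace A `signal_trace`.
#' @return The standardized `signal_trace`; median 0 and IQR 1 unless
#'   degenerate.
#' @export
robust_standardize <- function(trace) {
  x <- trace$samples
  med <- stats::median(x)
  iqr <- stats::IQR(x)
  if (iqr > 0) {
    out <- signal_trace((x - med) / iqr, trace$rate_hz, trace$name,
                        trace$kind)
  } else {
    out <- signal_trace(x - med, trace$rate_hz, trace$name, trace$kind)
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Correct heart-rate outliers caused by R-peak misdetection
#'
#' A sample is invalid when it leaves the physiological range
#' `[25, 220]` bpm or differs from a 5 s rolling median by more than
#' 30 bpm.  Invalid samples are replaced by linear interpolation between
#' neighbouring valid samples (nearest valid value at the record edges).
#' When more than half of the samples are invalid the returned trace
#' carries attribute `flagged = TRUE` for the quality report.
#'
#' @param hr A `signal_trace` in beats per minute (pre-standardization).
#' @param lo,hi Physiological bounds in bpm.
#' @param jump_bpm Maximum allowed deviation from the rolling median.
#' @param window_s Rolling-median window in seconds.
#' @return The corrected `signal_trace`; all samples within `[lo, hi]`.
#' @export
correct_hr_outliers <- function(hr, lo = 25, hi = 220, jump_bpm = 30,
                                window_s = 5) {
  x <- hr$samples
  n <- length(x)
  if (n == 0L) stop("empty heart-rate trace")
  k <- max(3L, round(window_s * hr$rate_hz))
  if (k %% 2L == 0L) k <- k + 1L
  k <- min(k, if (n %% 2L == 1L) n else n - 1L)
  roll <- if (n >= 3L && k >= 3L) {
    as.numeric(stats::runmed(x, k, endrule = "median"))
  } else x
  bad <- is.na(x) | x < lo | x > hi | abs(x - roll) > jump_bpm
  if (all(bad)) {
    out <- signal_trace(rep(pmin(pmax(stats::median(x, na.rm = TRUE), lo), hi),
                            n), hr$rate_hz, hr$name, hr$kind)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  if (any(bad)) {
    good_idx <- which(!bad)
    x[bad] <- stats::approx(good_idx, x[good_idx], xout = which(bad),
                            method = "linear", rule = 2)$y
  }
  x <- pmin(pmax(x, lo), hi)
  out <- signal_trace(x, hr$rate_hz, hr$name, hr$kind)
  if (mean(bad) > 0.5) attr(out, "flagged") <- TRUE
  out
}

#' Derive the binary wake/sleep trace from a hypnogram
#'
#' Each 30 s epoch's label is replicated across its samples: 1 during
#' sleep, 0 during wake.
#'
#' @param hyp A `hypnogram`.
#' @param target_rate Output sampling rate in Hz.
#' @param duration_s Optional duration to truncate/limit the trace to;
#'   defaults to the full hypnogram span.
#' @return A binary `signal_trace` at `target_rate`.
#' @export
derive_wake_sleep <- function(hyp, target_rate = 4, duration_s = NULL) {
  sleep <- as.numeric(epoch_is_sleep(hyp))
  total <- length(sleep) * 30
  if (is.null(duration_s)) duration_s <- total
  if (duration_s > total + 1e-9) {
    stop("hypnogram does not cover the requested duration")
  }
  n <- round(duration_s * target_rate)
  t <- (seq_len(n) - 1) / target_rate
  epoch <- pmin(floor(t / 30) + 1L, length(sleep))
  signal_trace(sleep[epoch], target_rate, "WS", "binary")
}

#' Derive the binary position-change trace
#'
#' Emits 1 exactly at samples where the position code differs from the
#' previous sample (the first sample is 0).
#'
#' @param pos A piecewise-constant `signal_trace` of position codes.
#' @return A binary `signal_trace` at the same rate.
#' @export
derive_position_change <- function(pos) {
  x <- pos$samples
  chg <- if (length(x) <= 1L) rep(0, length(x)) else
    c(0, as.numeric(diff(x) != 0))
  signal_trace(chg, pos$rate_hz, "Pos_chg", "binary")
}

# Longest-run helper: fraction of `idx` samples sitting in a constant run
# longer than `min_run` samples.
flat_run_mask <- function(x, min_run) {
  n <- length(x)
  if (n == 0L) return(logical(0))
  r <- rle(x)
  rep(r$lengths > min_run, r$lengths)
}

#' Assess per-channel signal quality and the record inclusion rule
#'
#' The bad fraction of a channel is the share of *sleep-time* samples that
#' are missing (`NA`), flat for more than 5 s, or outside a physiological
#' range (applied to `DHR` only: 25-220 bpm).  Binary/categorical channels
#' are piecewise-constant by nature and are exempt from the flat-line rule.
#' A record is included iff no selected channel has a bad fraction above
#' 0.5 (strictly more than 50% of sleep time excludes).
#'
#' @param rec A `recording`.
#' @param hyp The record's `hypnogram`.
#' @param selected_channels Channel names entering the model.
#' @return A `quality_report` list: `record_id`,
#'   `per_channel_bad_fraction`, `include`.
#' @export
assess_quality <- function(rec, hyp, selected_channels = names(rec$channels)) {
  missing_ch <- setdiff(selected_channels, names(rec$channels))
  if (length(missing_ch) > 0L) {
    stop("selected channel(s) not present: ", paste(missing_ch, collapse = ", "))
  }
  sleep <- epoch_is_sleep(hyp)
  frac <- vapply(selected_channels, function(nm) {
    tr <- rec$channels[[nm]]
    t <- (seq_along(tr$samples) - 1) / tr$rate_hz
    epoch <- pmin(floor(t / 30) + 1L, length(sleep))
    in_sleep <- sleep[epoch]
    if (!any(in_sleep)) return(0)
    x <- tr$samples
    bad <- is.na(x)
    if (!(tr$kind %in% c("binary", "categorical"))) {
      bad <- bad | flat_run_mask(x, round(5 * tr$rate_hz))
    }
    if (nm == "DHR") bad <- bad | x < 25 | x > 220
    mean(bad[in_sleep])
  }, numeric(1))
  structure(list(record_id = rec$record_id,
                 per_channel_bad_fraction = frac,
                 include = !any(frac > 0.5)),
            class = "quality_report")
}

#' Per-second labels and sleep mask from annotations
#'
#' `labels_1hz[t]` is 1 iff the second `[t, t+1)` intersects any
#' ground-truth event; `sleep_mask_1hz[t]` is 1 iff second `t` lies in a
#' sleep epoch.  Seconds are 0-based, so entry `i` of each vector covers
#' `[i-1, i)`.
#'
#' @param events Ground-truth `event_list` (must not overlap).
#' @param hyp The record's `hypnogram`.
#' @param duration_s Record duration; labels have length
#'   `floor(duration_s)`.
#' @return A list with numeric vectors `labels_1hz` and `sleep_mask_1hz`.
#' @export
make_labels <- function(events, hyp, duration_s) {
  validate_event_list(events)
  n <- floor(duration_s)
  if (nrow(events) > 0L &&
      (min(events$onset) < 0 || max(events$offset) > duration_s + 1e-9)) {
    stop("events must lie within [0, duration_s]")
  }
  labels <- numeric(n)
  for (i in seq_len(nrow(events))) {
    lo <- floor(events$onset[i])
    hi <- ceiling(events$offset[i]) - 1
    # second t intersects [onset, offset) iff onset < t+1 and offset > t
    ts <- lo:hi
    ts <- ts[events$onset[i] < ts + 1 & events$offset[i] > ts & ts >= 0 &
               ts < n]
    labels[ts + 1L] <- 1
  }
  sleep <- epoch_is_sleep(hyp)
  t <- seq_len(n) - 1L
  epoch <- pmin(floor(t / 30) + 1L, length(sleep))
  list(labels_1hz = labels, sleep_mask_1hz = as.numeric(sleep[epoch]))
}

#' Preprocess a recording into model-ready channels
#'
#' Applies the full preprocessing chain: resample every selected channel to
#' 4 Hz, correct heart-rate outliers (on `DHR`, before standardization),
#' median/IQR-standardize continuous channels (binary channels keep their
#' 0/1 coding), and derive per-second labels and sleep mask.
#'
#' @param rec A `recording`.
#' @param hyp The record's `hypnogram`.
#' @param events Ground-truth arousal `event_list` (may be empty).
#' @param selected_channels Channels to retain, default all present.
#' @return A `preprocessed_record`: `record_id`, `x` (a `4*T` by
#'   `n_channels` matrix of 4 Hz samples, columns named), `labels_1hz`,
#'   `sleep_mask_1hz`, `wake_sleep_4hz`, `quality`.
#' @export
preprocess_record <- function(rec, hyp, events,
                              selected_channels = names(rec$channels)) {
  quality <- assess_quality(rec, hyp, selected_channels)
  dur <- floor(rec$duration_s)
  n4 <- dur * 4L
  cols <- lapply(selected_channels, function(nm) {
    tr <- resample_to_4hz(rec$channels[[nm]])
    if (nm == "DHR") tr <- correct_hr_outliers(tr)
    if (!(nm %in% CATEGORICAL_CHANNELS) || nm == "Pos") {
      # Pos is categorical but enters the model as a standardized level
      tr <- robust_standardize(tr)
    }
    x <- tr$samples
    length(x) <- n4
    x[is.na(x)] <- 0
    x
  })
  x <- do.call(cbind, cols)
  colnames(x) <- selected_channels
  lab <- make_labels(events, hyp, dur)
  ws <- derive_wake_sleep(hyp, 4, dur)
  structure(list(record_id = rec$record_id, x = x,
                 labels_1hz = lab$labels_1hz,
                 sleep_mask_1hz = lab$sleep_mask_1hz,
                 wake_sleep_4hz = ws$samples,
                 quality = quality),
            class = "preprocessed_record")
}
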