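#' @title Core containers for limited-channel sleep recordings
#' @name hstarousal-types
#' @description
#' The package works with four small S3 containers: `signal_trace` (one
#' sampled channel), `recording` (a named set of traces), `hypnogram`
#' (30 s epoch stages) and `event_list` (sorted, non-overlapping, half-open
#' time intervals in seconds).  All times are seconds from record start,
#' 0-based; an interval `[onset, offset)` excludes its offset.
NULL

# Channel names the pipeline knows about.  WS and Pos_chg are binary, Pos is
# categorical; the rest are continuous.
CHANNEL_NAMES <- c("Thor", "DHR", "Snore", "Pos", "Pos_chg", "WS")
BINARY_CHANNELS <- c("WS", "Pos_chg")
CATEGORICAL_CHANNELS <- c("Pos", "Pos_chg", "WS")

#' Construct a single-channel signal trace
#'
#' @param samples Numeric vector of samples.
#' @param rate_hz Sampling rate in Hz (> 0).
#' @param name Channel label.
#' @param kind `"continuous"` (resampled by linear interpolation) or
#'   `"binary"` / `"categorical"` (resampled by nearest neighbour).
#' @return An object of class `signal_trace`.
#' @export
signal_trace <- function(samples, rate_hz, name = "signal",
                         kind = c("continuous", "binary", "categorical")) {
  kind <- match.arg(kind)
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0) {
    stop("rate_hz must be a single positive number")
  }
  structure(
    list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
         name = name, kind = kind),
    class = "signal_trace"
  )
}

#' @export
print.signal_trace <- function(x, ...) {
  cat(sprintf("<signal_trace '%s'> %d samples @ %g Hz (%.1f s, %s)\n",
              x$name, length(x$samples), x$rate_hz,
              length(x$samples) / x$rate_hz, x$kind))
  invisible(x)
}

#' Duration of a trace in seconds
#' @param trace A `signal_trace`.
#' @return Duration in seconds.
#' @export
trace_duration <- function(trace) length(trace$samples) / trace$rate_hz

#' Construct a multichannel recording
#'
#' @param record_id Identifier string.
#' @param channels Named list of `signal_trace` objects; names must come from
#'   `Thor`, `DHR`, `Snore`, `Pos`, `Pos_chg`, `WS`.
#' @param duration_s Recording duration in seconds.  All channel durations
#'   must agree with it within one sample period.
#' @return An object of class `recording`.
#' @export
recording <- function(record_id, channels, duration_s) {
  stopifnot(is.character(record_id), length(record_id) == 1L)
  if (!all(names(channels) %in% CHANNEL_NAMES)) {
    stop("channel names must be drawn from: ",
         paste(CHANNEL_NAMES, collapse = ", "))
  }
  for (nm in names(channels)) {
    tr <- channels[[nm]]
    stopifnot(inherits(tr, "signal_trace"))
    if (abs(trace_duration(tr) - duration_s) > 1 / tr$rate_hz) {
      stop(sprintf("channel '%s' duration %.3f s disagrees with %.3f s",
                   nm, trace_duration(tr), duration_s))
    }
  }
  structure(list(record_id = record_id, channels = channels,
                 duration_s = duration_s),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording '%s'> %.1f s, channels: %s\n", x$record_id,
              x$duration_s, paste(names(x$channels), collapse = ", ")))
  invisible(x)
}

# Hypnogram stage codes: "W" plus the AASM sleep stages.
STAGE_CODES <- c("W", "N1", "N2", "N3", "R")

#' Construct a hypnogram (30 s epoch stage sequence)
#'
#' @param stages Character vector of per-epoch codes among
#'   `W, N1, N2, N3, R`.
#' @return An object of class `hypnogram`.
#' @export
hypnogram <- function(stages) {
  stages <- as.character(stages)
  if (length(stages) == 0L) stop("hypnogram must contain at least one epoch")
  bad <- setdiff(unique(stages), STAGE_CODES)
  if (length(bad) > 0L) {
    stop("unknown stage code(s): ", paste(bad, collapse = ", "))
  }
  structure(list(stages = stages), class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  n <- length(x$stages)
  cat(sprintf("<hypnogram> %d epochs (%.1f h), %.1f%% wake\n", n,
              n * 30 / 3600, 100 * mean(x$stages == "W")))
  invisible(x)
}

#' Per-epoch sleep indicator of a hypnogram
#' @param hyp A `hypnogram`.
#' @return Logical vector, `TRUE` for sleep epochs.
#' @export
epoch_is_sleep <- function(hyp) hyp$stages != "W"

#' Construct a sorted, non-overlapping event list
#'
#' Events are half-open intervals `[onset, offset)` in seconds.  Onsets must
#' be strictly increasing, intervals non-overlapping and non-empty.
#'
#' @param onset,offset Numeric vectors of equal length (possibly empty).
#' @return An object of class `event_list`: a data frame with columns
#'   `onset` and `offset`.
#' @export
event_list <- function(onset = numeric(0), offset = numeric(0)) {
  stopifnot(length(onset) == length(offset))
  df <- data.frame(onset = as.numeric(onset), offset = as.numeric(offset))
  class(df) <- c("event_list", "data.frame")
  validate_event_list(df)
  df
}

#' Validate event-list invariants
#' @param events An `event_list`.
#' @return The input, invisibly, or an error.
#' @export
validate_event_list <- function(events) {
  if (nrow(events) == 0L) return(invisible(events))
  if (any(events$offset <= events$onset)) {
    stop("every event must satisfy offset > onset")
  }
  if (nrow(events) > 1L) {
    if (any(diff(events$onset) <= 0)) {
      stop("event onsets must be strictly increasing")
    }
    if (any(events$onset[-1L] < events$offset[-nrow(events)])) {
      stop("events must not overlap")
    }
  }
  invisible(events)
}

#' @export
print.event_list <- function(x, ...) {
  cat(sprintf("<event_list> %d events\n", nrow(x)))
  if (nrow(x) > 0L) print(format(as.data.frame(x), digits = 4), ...)
  invisible(x)
}

#' Number of events in an event list
#' @param events An `event_list`.
#' @return Integer count.
#' @export
n_events <- function(events) nrow(events)

#' Event durations in seconds
#' @param events An `event_list`.
#' @return Numeric vector of durations.
#' @export
event_durations <- function(events) events$offset - events$onset

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a child seed from a master seed and a string tag; stays below 2^31.
derive_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h * 131) %% 2147483597L + 1)
}
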