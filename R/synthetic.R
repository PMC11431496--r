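#' Configuration for the synthetic limited-channel recording generator
#'
#' The generator emulates the signal set a limited-channel home sleep test
#' records — thoracic effort (`Thor`), ECG-derived heart rate (`DHR`),
#' cannula snore vibration (`Snore`), body position (`Pos`), position change
#' (`Pos_chg`) and a hypnogram-derived wake/sleep indicator (`WS`) — plus
#' ground-truth arousal events carrying the autonomic signatures a detector
#' can exploit: a transient heart-rate surge, a thoracic amplitude/rate
#' change, and snore interruption.
#'
#' @param duration_s Recording duration in seconds (default one hour).
#' @param arousal_rate Target arousal rate in events per hour of sleep.
#'   A middle-aged cohort typically scores in the 10-25/h range; default 15.
#' @param arousal_duration_range Two-element `(min_s, max_s)` event duration
#'   range; minimum must be >= 3 s (the AASM minimum duration).
#' @param min_event_gap_s Minimum gap between ground-truth events; must be
#'   >= 10 s so that truth can never be altered by the 5 s merge rule.
#' @param hr_surge_bpm Peak additive tachycardia during an arousal, in bpm.
#' @param thor_amplitude_factor Multiplicative thoracic-effort amplitude
#'   factor applied during an arousal (> 1 means deeper excursions).
#' @param snore_probability Per-epoch probability that snoring is active
#'   during a sleep epoch.
#' @param wake_fraction Stationary proportion of 30 s epochs scored Wake.
#' @param noise_sd_per_channel Named numeric vector of additive Gaussian
#'   noise standard deviations for `Thor`, `DHR` (bpm) and `Snore`.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(duration_s = 3600,
                             arousal_rate = 15,
                             arousal_duration_range = c(5, 15),
                             min_event_gap_s = 30,
                             hr_surge_bpm = 10,
                             thor_amplitude_factor = 1.6,
                             snore_probability = 0.3,
                             wake_fraction = 0.15,
                             noise_sd_per_channel = c(Thor = 0.1, DHR = 1,
                                                      Snore = 0.05),
                             seed = 1L) {
  stopifnot(length(arousal_duration_range) == 2L)
  if (arousal_duration_range[1] < 3) {
    stop("arousal_duration_range minimum must be >= 3 s (AASM minimum)")
  }
  if (arousal_duration_range[2] < arousal_duration_range[1]) {
    stop("arousal_duration_range must be (min, max) with max >= min")
  }
  if (min_event_gap_s < 10) {
    stop("min_event_gap_s must be >= 10 s so the 5 s merge rule cannot ",
         "alter ground truth")
  }
  if (arousal_rate < 0) stop("arousal_rate must be >= 0")
  if (wake_fraction < 0 || wake_fraction > 1) {
    stop("wake_fraction must be in [0, 1]")
  }
  if (duration_s < 30) stop("duration_s must cover at least one 30 s epoch")
  ns <- c(Thor = 0.1, DHR = 1, Snore = 0.05)
  ns[names(noise_sd_per_channel)] <- noise_sd_per_channel
  structure(list(
    duration_s = duration_s,
    arousal_rate = arousal_rate,
    arousal_duration_range = arousal_duration_range,
    min_event_gap_s = min_event_gap_s,
    hr_surge_bpm = hr_surge_bpm,
    thor_amplitude_factor = thor_amplitude_factor,
    snore_probability = snore_probability,
    wake_fraction = wake_fraction,
    noise_sd_per_channel = ns,
    seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Read a synthetic-generator configuration from a YAML file
#'
#' Keys mirror the arguments of [synthetic_config()]; the
#' `noise_sd_per_channel` entry may be a nested mapping.
#'
#' @param path Path to a YAML file.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$noise_sd_per_channel)) {
    raw$noise_sd_per_channel <- unlist(raw$noise_sd_per_channel)
  }
  if (!is.null(raw$arousal_duration_range)) {
    raw$arousal_duration_range <- as.numeric(unlist(raw$arousal_duration_range))
  }
  do.call(synthetic_config, raw)
}

# Two-state Markov hypnogram with the requested stationary wake fraction and
# sticky bouts (mean wake bout ~ 5 epochs).  Sleep epochs get plausible
# stage labels; only the wake/sleep distinction matters downstream.
generate_hypnogram <- function(n_epochs, wake_fraction) {
  if (wake_fraction <= 0) {
    return(hypnogram(sample(c("N1", "N2", "N2", "N2", "N3", "R"),
                            n_epochs, replace = TRUE)))
  }
  if (wake_fraction >= 1) return(hypnogram(rep("W", n_epochs)))
  p_ww <- 0.8  # wake persistence
  # stationary wake fraction f solves f = f*p_ww + (1-f)*p_sw
  p_sw <- wake_fraction * (1 - p_ww) / (1 - wake_fraction)
  p_sw <- min(p_sw, 1)
  awake <- logical(n_epochs)
  awake[1] <- runif(1) < wake_fraction
  for (i in seq_len(n_epochs - 1L)) {
    p <- if (awake[i]) p_ww else p_sw
    awake[i + 1L] <- runif(1) < p
  }
  stages <- ifelse(awake, "W",
                   sample(c("N1", "N2", "N2", "N2", "N3", "R"),
                          n_epochs, replace = TRUE))
  hypnogram(stages)
}

# Rejection-sample non-overlapping arousal events inside sleep epochs:
# onsets are drawn uniformly over sleep time (so wake periods cost no
# attempts); a draw is rejected when the event would straddle a wake epoch,
# overrun the record, or come closer than the minimum gap to an accepted
# event.  The target count is round(arousal_rate x sleep hours) so the
# configured rate is the realized per-record rate (placement noise aside);
# sampling stops when the target is met or after 10x as many attempts.
place_events <- function(config, hyp) {
  dur <- config$duration_s
  sleep <- epoch_is_sleep(hyp)
  sleep_hours <- sum(sleep) * 30 / 3600
  target <- if (config$arousal_rate <= 0 || sleep_hours <= 0) 0L else
    as.integer(round(config$arousal_rate * sleep_hours))
  if (target == 0L) return(event_list())
  sleep_starts <- (which(sleep) - 1L) * 30
  onsets <- numeric(0)
  offsets <- numeric(0)
  attempts <- 0L
  max_attempts <- 10L * target
  rng <- config$arousal_duration_range
  while (length(onsets) < target && attempts < max_attempts) {
    attempts <- attempts + 1L
    d <- runif(1, rng[1], rng[2])
    # uniform over sleep time: pick a sleep epoch, then an offset inside it
    on <- sample(sleep_starts, 1L) + runif(1, 0, 30)
    off <- on + d
    if (off > dur) next
    epochs <- seq.int(floor(on / 30), ceiling(off / 30) - 1) + 1L
    if (any(epochs > length(sleep)) || !all(sleep[epochs])) next
    if (length(onsets) > 0) {
      gap_ok <- all(on - offsets >= config$min_event_gap_s |
                    onsets - off >= config$min_event_gap_s)
      if (!gap_ok) next
    }
    onsets <- c(onsets, on)
    offsets <- c(offsets, off)
  }
  o <- order(onsets)
  event_list(onsets[o], offsets[o])
}

# Per-sample additive heart-rate arousal response: 2 s linear onset ramp to
# hr_surge_bpm, plateau for the rest of the event, exponential decay
# (tau = 5 s) after offset, truncated at 10 s post-event.
hr_response <- function(t, events, surge) {
  resp <- numeric(length(t))
  if (nrow(events) == 0L || surge == 0) return(resp)
  for (i in seq_len(nrow(events))) {
    on <- events$onset[i]; off <- events$offset[i]
    ramp <- pmin(2, (off - on) / 2)
    inside <- t >= on & t < off
    resp[inside] <- pmax(resp[inside],
                         surge * pmin((t[inside] - on) / ramp, 1))
    tail <- t >= off & t < off + 10
    resp[tail] <- pmax(resp[tail], surge * exp(-(t[tail] - off) / 5))
  }
  resp
}

# 0/1 indicator of membership in any [onset, offset) event, per sample.
event_indicator <- function(t, events) {
  ind <- numeric(length(t))
  for (i in seq_len(nrow(events))) {
    ind[t >= events$onset[i] & t < events$offset[i]] <- 1
  }
  ind
}

#' Generate one synthetic limited-channel recording
#'
#' Channels (all at 4 Hz):
#' * `Thor` — quasi-periodic respiratory effort (~0.25 Hz, jittered in rate
#'   and amplitude); during each ground-truth arousal the amplitude is
#'   multiplied by `thor_amplitude_factor` and the respiratory rate rises.
#' * `DHR` — baseline heart rate (~62 bpm with slow drift) plus an additive
#'   surge of `hr_surge_bpm` during each event, decaying exponentially
#'   (tau = 5 s) for at most 10 s afterwards.
#' * `Snore` — oscillatory bursts gated per 30 s epoch (probability
#'   `snore_probability`, sleep epochs only), suppressed during events.
#' * `Pos` — piecewise-constant position code with occasional transitions.
#' * `Pos_chg` — 1 at samples where `Pos` changes, else 0.
#' * `WS` — 1 during sleep epochs, 0 during wake epochs.
#'
#' Ground-truth events fall only inside sleep epochs, satisfy the configured
#' duration range and minimum gap, and the output is deterministic given
#' `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `recording`, `hypnogram`, `events`.
#' @export
generate_recording <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(config$seed, {
    fs <- 4
    dur <- config$duration_s
    n <- round(dur * fs)
    t <- (seq_len(n) - 1) / fs
    n_epochs <- ceiling(dur / 30)
    hyp <- generate_hypnogram(n_epochs, config$wake_fraction)
    events <- place_events(config, hyp)
    ind <- event_indicator(t, events)
    ns <- config$noise_sd_per_channel

    # --- Thor: amplitude/frequency-jittered sinusoid --------------------
    base_f <- 0.25
    f_jit <- stats::filter(rnorm(n, 0, 0.005), rep(1, 8), sides = 1)
    f_jit[is.na(f_jit)] <- 0
    freq <- pmax(base_f + as.numeric(f_jit), 0.15)
    freq <- freq * (1 + 0.3 * ind)         # arousal raises respiratory rate
    phase <- cumsum(2 * pi * freq / fs)
    amp_slow <- 1 + 0.15 * sin(2 * pi * t / 300 + runif(1, 0, 2 * pi))
    amp <- amp_slow * (1 + (config$thor_amplitude_factor - 1) * ind)
    thor <- amp * sin(phase) + rnorm(n, 0, ns[["Thor"]])

    # --- DHR: baseline + arousal tachycardia ----------------------------
    hr_base <- 62 + 2 * sin(2 * pi * t / 600 + runif(1, 0, 2 * pi))
    dhr <- hr_base + hr_response(t, events, config$hr_surge_bpm) +
      rnorm(n, 0, ns[["DHR"]])

    # --- Snore: epoch-gated bursts, interrupted by arousals -------------
    sleep_epochs <- epoch_is_sleep(hyp)
    snoring_epoch <- sleep_epochs & (runif(n_epochs) < config$snore_probability)
    epoch_of_sample <- pmin(floor(t / 30) + 1L, n_epochs)
    gate <- as.numeric(snoring_epoch[epoch_of_sample]) * (1 - ind)
    snore <- gate * sin(2 * pi * 1.5 * t) * abs(sin(phase)) +
      rnorm(n, 0, ns[["Snore"]])

    # --- Pos / Pos_chg --------------------------------------------------
    n_moves <- rpois(1L, max(dur / 3600, 0.1) * 4)   # ~4 position changes/h
    move_times <- sort(runif(n_moves, 0, dur))
    pos <- integer(n)
    code <- sample(0:3, 1L)
    prev_t <- 0
    for (mt in c(move_times, Inf)) {
      seg <- t >= prev_t & t < mt
      pos[seg] <- code
      nxt <- sample(setdiff(0:3, code), 1L)
      code <- nxt
      prev_t <- mt
    }
    pos_chg <- c(0, as.numeric(diff(pos) != 0))

    # --- WS -------------------------------------------------------------
    ws <- as.numeric(sleep_epochs[epoch_of_sample])

    rec <- recording(
      record_id = sprintf("synth-%08x", as.integer(config$seed)),
      channels = list(
        Thor = signal_trace(thor, fs, "Thor", "continuous"),
        DHR = signal_trace(dhr, fs, "DHR", "continuous"),
        Snore = signal_trace(snore, fs, "Snore", "continuous"),
        Pos = signal_trace(pos, fs, "Pos", "categorical"),
        Pos_chg = signal_trace(pos_chg, fs, "Pos_chg", "binary"),
        WS = signal_trace(ws, fs, "WS", "binary")
      ),
      duration_s = dur
    )
    list(recording = rec, hypnogram = hyp, events = events)
  })
}

#' Generate a cohort of synthetic recordings
#'
#' Each record uses a seed derived from `config$seed` and its index, so the
#' cohort is reproducible as a whole while records are independent draws.
#'
#' @param n_records Number of recordings (>= 1).
#' @param config A [synthetic_config()] shared by all records.
#' @return A list of `n_records` elements, each as from
#'   [generate_recording()].
#' @export
generate_cohort <- function(n_records, config) {
  stopifnot(n_records >= 1)
  lapply(seq_len(n_records), function(i) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(config$seed, paste0("record-", i))
    out <- generate_recording(cfg_i)
    out$recording$record_id <- sprintf("synth-%04d", i)
    out
  })
}

#' Randomly flip wake/sleep epoch labels
#'
#' Used for wake/sleep misclassification robustness studies: each epoch's
#' wake/sleep status is independently flipped with probability `error_rate`
#' (a flipped sleep epoch becomes `W`; a flipped wake epoch becomes `N2` —
#' stage detail beyond the wake/sleep distinction is not preserved).
#'
#' @param hyp A `hypnogram`.
#' @param error_rate Flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A corrupted `hypnogram` of the same length.
#' @export
corrupt_wake_sleep <- function(hyp, error_rate, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 1)
  with_seed(seed, {
    flip <- runif(length(hyp$stages)) < error_rate
    stages <- hyp$stages
    stages[flip] <- ifelse(stages[flip] == "W", "N2", "W")
    hypnogram(stages)
  })
}
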