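# Shared fixtures: small configs sized for fast unit tests.

tiny_model_config <- function(n_channels = 2L, seed = 1L) {
  model_config(n_input_channels = n_channels,
               inception_filters_per_branch = 2L,
               residual_channels = 4L, lstm_hidden = 4L, seed = seed)
}

small_synth_config <- function(seed = 1L, duration_s = 600, ...) {
  synthetic_config(duration_s = duration_s, seed = seed, ...)
}

# High signal-to-noise study conditions used by the end-to-end learning
# tests: strong autonomic signatures in Thor and DHR, low channel noise.
high_snr_config <- function(seed = 1L, duration_s = 1200) {
  synthetic_config(duration_s = duration_s, arousal_rate = 20,
                   wake_fraction = 0.1, hr_surge_bpm = 12,
                   thor_amplitude_factor = 1.8,
                   noise_sd_per_channel = c(Thor = 0.05, DHR = 0.5,
                                            Snore = 0.02),
                   seed = seed)
}

# Brute-force all-pairs event matcher: the independent oracle for
# match_events (O(n*m), no sorting assumptions).
brute_force_match <- function(gt, det, omega_min = 0.5) {
  n_gt <- nrow(gt); n_det <- nrow(det)
  gt_hit <- logical(n_gt); det_hit <- logical(n_det)
  for (i in seq_len(n_gt)) {
    for (j in seq_len(n_det)) {
      ov <- min(gt$offset[i], det$offset[j]) - max(gt$onset[i], det$onset[j])
      if (ov > 0 && ov / (gt$offset[i] - gt$onset[i]) > omega_min) {
        gt_hit[i] <- TRUE
        det_hit[j] <- TRUE
      }
    }
  }
  list(tp = sum(det_hit), fp = n_det - sum(det_hit), fn = sum(!gt_hit),
       gt_matched = sum(gt_hit))
}

# Random valid event list on [0, horizon): sorted, non-overlapping.
random_event_list <- function(n, horizon = 1000) {
  if (n == 0) return(event_list())
  pts <- sort(runif(2 * n, 0, horizon))
  on <- pts[seq(1, 2 * n, by = 2)]
  off <- pts[seq(2, 2 * n, by = 2)]
  keep <- off - on > 1e-3
  event_list(on[keep], off[keep])
}

# Synthetic probability sequence whose event-F1 landscape is (generically)
# unimodal: near-zero background, constant-height true events spread over
# high probabilities and distractor bumps spread over a disjoint low range,
# so F1 rises while distractors drop out and falls while true events do.
threshold_landscape_case <- function(seed) {
  set.seed(seed)
  n <- 1300
  probs <- rep(0.001, n)
  lab <- numeric(n)
  slot <- seq(5, n - 30, by = 26)
  truth <- seq_along(slot) %% 2 == 1
  h_true <- seq(0.42, 0.95, length.out = sum(truth)) +
    runif(sum(truth), -0.01, 0.01)
  h_dis <- seq(0.05, 0.38, length.out = sum(!truth)) +
    runif(sum(!truth), -0.01, 0.01)
  it <- 0; id <- 0
  for (k in seq_along(slot)) {
    at <- slot[k] + seq_len(sample(4:7, 1))
    if (truth[k]) {
      it <- it + 1; probs[at] <- h_true[it]; lab[at] <- 1
    } else {
      id <- id + 1; probs[at] <- h_dis[id]
    }
  }
  list(probs = pmin(pmax(probs, 0.001), 0.999),
       events = seconds_to_events(lab))
}
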