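test_that("zero arousal rate yields an empty event list and flat DHR", {
  cfg <- small_synth_config(seed = 5, arousal_rate = 0,
                            noise_sd_per_channel = c(DHR = 0))
  g <- generate_recording(cfg)
  expect_equal(n_events(g$events), 0L)
  # no surges: DHR stays within the slow baseline drift band (62 +/- 2)
  expect_lt(max(g$recording$channels$DHR$samples), 65)
  expect_gt(min(g$recording$channels$DHR$samples), 59)
})

test_that("wake_fraction 0 gives an all-sleep WS channel; 1 gives all wake", {
  g0 <- generate_recording(small_synth_config(seed = 2, wake_fraction = 0))
  expect_true(all(g0$recording$channels$WS$samples == 1))
  expect_true(all(epoch_is_sleep(g0$hypnogram)))
  g1 <- generate_recording(small_synth_config(seed = 2, wake_fraction = 1))
  expect_true(all(g1$recording$channels$WS$samples == 0))
  expect_equal(n_events(g1$events), 0L)
})

test_that("event count at rate 10/h over 1 h sleep falls in the Poisson 99% interval", {
  cfg <- synthetic_config(duration_s = 3600, arousal_rate = 10,
                          wake_fraction = 0, seed = 31)
  g <- generate_recording(cfg)
  # independent count of placed events vs the target rate
  n <- n_events(g$events)
  interval <- qpois(c(0.005, 0.995), lambda = 10)
  expect_gte(n, interval[1])
  expect_lte(n, interval[2])
})

test_that("generation is bitwise deterministic given the seed", {
  cfg <- small_synth_config(seed = 77)
  a <- generate_recording(cfg)
  b <- generate_recording(cfg)
  expect_identical(a, b)
  ca <- generate_cohort(3, cfg)
  cb <- generate_cohort(3, cfg)
  expect_identical(ca, cb)
})

test_that("cohort records have unique ids and distinct draws", {
  coh <- generate_cohort(3, small_synth_config(seed = 9))
  ids <- vapply(coh, function(g) g$recording$record_id, character(1))
  expect_equal(length(unique(ids)), 3L)
  expect_false(identical(coh[[1]]$recording$channels$Thor$samples,
                         coh[[2]]$recording$channels$Thor$samples))
})

test_that("ground-truth events respect duration, gap and sleep-only placement", {
  for (seed in 1:100) {
    cfg <- synthetic_config(duration_s = 900, arousal_rate = 25,
                            wake_fraction = 0.2, seed = seed)
    g <- generate_recording(cfg)
    ev <- g$events
    if (nrow(ev) == 0) next
    expect_true(all(event_durations(ev) >= cfg$arousal_duration_range[1] - 1e-9))
    expect_true(all(event_durations(ev) <= cfg$arousal_duration_range[2] + 1e-9))
    if (nrow(ev) > 1) {
      gaps <- ev$onset[-1] - ev$offset[-nrow(ev)]
      expect_true(all(gaps >= cfg$min_event_gap_s - 1e-9))
    }
    sleep <- epoch_is_sleep(g$hypnogram)
    for (i in seq_len(nrow(ev))) {
      epochs <- (floor(ev$onset[i] / 30)):(ceiling(ev$offset[i] / 30) - 1) + 1
      expect_true(all(sleep[epochs]))
    }
  }
})

test_that("DHR effect size is recovered within 15% at zero noise", {
  cfg <- synthetic_config(duration_s = 3600, arousal_rate = 20,
                          wake_fraction = 0, hr_surge_bpm = 10,
                          noise_sd_per_channel = c(Thor = 0, DHR = 0,
                                                   Snore = 0),
                          seed = 13)
  g <- generate_recording(cfg)
  t <- (seq_along(g$recording$channels$DHR$samples) - 1) / 4
  inside <- rep(FALSE, length(t))
  for (i in seq_len(nrow(g$events))) {
    inside <- inside | (t >= g$events$onset[i] & t < g$events$offset[i])
  }
  expect_gt(sum(inside), 0)
  dhr <- g$recording$channels$DHR$samples
  effect <- mean(dhr[inside]) - mean(dhr[!inside])
  expect_lt(abs(effect - 10) / 10, 0.15)
})

test_that("pooled cohort arousal index is within 10% of the configured rate", {
  cfg <- synthetic_config(duration_s = 1800, arousal_rate = 20,
                          wake_fraction = 0.1, seed = 3)
  coh <- generate_cohort(50, cfg)
  events <- sum(vapply(coh, function(g) n_events(g$events), numeric(1)))
  sleep_h <- sum(vapply(coh, function(g) {
    sum(epoch_is_sleep(g$hypnogram)) * 30 / 3600
  }, numeric(1)))
  ari <- events / sleep_h
  expect_lt(abs(ari - 20) / 20, 0.10)
})

test_that("wake/sleep corruption flips no epochs at rate 0 and all at rate 1", {
  hyp <- generate_recording(small_synth_config(seed = 4))$hypnogram
  expect_identical(corrupt_wake_sleep(hyp, 0, seed = 1)$stages, hyp$stages)
  flipped <- corrupt_wake_sleep(hyp, 1, seed = 1)
  expect_identical(epoch_is_sleep(flipped), !epoch_is_sleep(hyp))
})

test_that("wake/sleep corruption at 30% flips a binomially plausible fraction", {
  hyp <- hypnogram(rep(c("W", "N2"), 500))
  out <- corrupt_wake_sleep(hyp, 0.3, seed = 11)
  frac <- mean(epoch_is_sleep(out) != epoch_is_sleep(hyp))
  expect_gte(frac, 0.26)   # binomial(1000, 0.3) 99% interval
  expect_lte(frac, 0.34)
})

test_that("generator config validates its invariants", {
  expect_error(synthetic_config(arousal_duration_range = c(2, 10)), "AASM")
  expect_error(synthetic_config(min_event_gap_s = 5), "merge")
  expect_error(synthetic_config(arousal_rate = -1))
  expect_error(synthetic_config(wake_fraction = 1.2))
  expect_error(synthetic_config(duration_s = 10), "epoch")
})

test_that("a YAML config round-trips through read_synthetic_config", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "duration_s: 600", "arousal_rate: 12",
    "arousal_duration_range: [4, 12]", "min_event_gap_s: 20",
    "hr_surge_bpm: 8", "wake_fraction: 0.2",
    "noise_sd_per_channel:", "  Thor: 0.2", "  DHR: 2.0", "seed: 99"
  ), path)
  cfg <- read_synthetic_config(path)
  expect_s3_class(cfg, "synthetic_config")
  expect_equal(cfg$arousal_rate, 12)
  expect_equal(cfg$noise_sd_per_channel[["DHR"]], 2)
  expect_equal(cfg$noise_sd_per_channel[["Snore"]], 0.05)  # default kept
  expect_equal(cfg$seed, 99L)
})
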