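test_that("resampling to 4 Hz preserves constants, identity and duration", {
  const <- signal_trace(rep(3.5, 320), 32, "Thor")
  out <- resample_to_4hz(const)
  expect_equal(out$rate_hz, 4)
  expect_true(all(out$samples == 3.5))
  expect_equal(trace_duration(out), 10)
  at4 <- signal_trace(rnorm(40), 4, "Thor")
  expect_identical(resample_to_4hz(at4), at4)
  expect_identical(resample_to_4hz(resample_to_4hz(const)),
                   resample_to_4hz(const))  # idempotence
  expect_error(resample_to_4hz(signal_trace(numeric(0), 4)), "empty")
})

test_that("upsampling a 1 Hz ramp matches linear interpolation on the 0.25 s grid", {
  ramp <- signal_trace(0:9, 1, "Thor")
  out <- resample_to_4hz(ramp)
  expect_equal(length(out$samples), 40)
  expect_true(all(diff(out$samples) >= 0))
  oracle <- approx((0:9), 0:9, xout = (0:39) / 4, rule = 2)$y
  expect_equal(out$samples, oracle)
})

test_that("binary channels are resampled by nearest neighbour (no fractions)", {
  tr <- signal_trace(c(0, 0, 1, 1, 0), 1, "WS", "binary")
  out <- resample_to_4hz(tr)
  expect_true(all(out$samples %in% c(0, 1)))
  expect_equal(length(out$samples), 20)
})

test_that("robust standardization gives median 0 and IQR 1, and is idempotent", {
  tr <- signal_trace(c(1, 2, 3, 4, 5), 4, "Thor")
  out <- robust_standardize(tr)
  expect_equal(median(out$samples), 0)
  expect_equal(IQR(out$samples), 1)
  again <- robust_standardize(out)
  expect_equal(again$samples, out$samples, tolerance = 1e-12)
})

test_that("standardizing a large normal sample centres the median", {
  set.seed(42)
  tr <- signal_trace(rnorm(1e5, 10, 5), 4, "Thor")
  out <- robust_standardize(tr)
  expect_gte(median(out$samples), -0.02)
  expect_lte(median(out$samples), 0.02)
  expect_equal(median(out$samples), as.numeric(quantile(out$samples, 0.5)))
})

test_that("a flat trace is median-centred and flagged degenerate", {
  out <- robust_standardize(signal_trace(rep(7, 100), 4, "Thor"))
  expect_true(all(out$samples == 0))
  expect_true(isTRUE(attr(out, "degenerate")))
})

test_that("heart-rate outlier correction repairs spikes and respects clean input", {
  clean <- signal_trace(rep(60, 400), 4, "DHR")
  expect_equal(correct_hr_outliers(clean)$samples, rep(60, 400))
  spiked <- clean
  spiked$samples[200] <- 300
  fixed <- correct_hr_outliers(spiked)
  expect_equal(fixed$samples[200], 60, tolerance = 1e-9)
  expect_true(all(fixed$samples >= 25 & fixed$samples <= 220))
})

test_that("spike correction reduces RMSE at least 10-fold on sinusoidal HR", {
  set.seed(7)
  t <- (0:4799) / 4
  clean <- 65 + 8 * sin(2 * pi * t / 120)
  corrupted <- clean
  spikes <- sample(length(t), length(t) * 0.01)
  corrupted[spikes] <- corrupted[spikes] + sample(c(-1, 1), length(spikes),
                                                  TRUE) * runif(length(spikes), 60, 150)
  fixed <- correct_hr_outliers(signal_trace(corrupted, 4, "DHR"))$samples
  rmse <- function(x) sqrt(mean((x - clean)^2))
  expect_lt(rmse(fixed) * 10, rmse(corrupted))
})

test_that("wake/sleep derivation replicates epochs at the target rate", {
  expect_true(all(derive_wake_sleep(hypnogram(rep("W", 4)))$samples == 0))
  tr <- derive_wake_sleep(hypnogram(c("W", "N2")), 4)
  expect_equal(tr$samples, c(rep(0, 120), rep(1, 120)))
  # brute-force per-sample epoch lookup oracle on random hypnograms
  set.seed(1)
  for (i in 1:10) {
    stages <- sample(c("W", "N1", "N2", "N3", "R"), 20, TRUE)
    hyp <- hypnogram(stages)
    tr <- derive_wake_sleep(hyp, 4)
    t <- (seq_along(tr$samples) - 1) / 4
    oracle <- as.numeric(stages[floor(t / 30) + 1] != "W")
    expect_identical(tr$samples, oracle)
  }
  expect_error(hypnogram(c("N2", "XX")), "unknown")
})

test_that("position-change derivation marks exactly the change samples", {
  expect_true(all(derive_position_change(
    signal_trace(rep(2, 50), 4, "Pos", "categorical"))$samples == 0))
  out <- derive_position_change(signal_trace(c(1, 1, 2, 2, 1), 4, "Pos",
                                             "categorical"))
  expect_equal(out$samples, c(0, 0, 1, 0, 1))
  set.seed(2)
  codes <- sample(0:3, 1e4, TRUE)
  out <- derive_position_change(signal_trace(codes, 4, "Pos", "categorical"))
  expect_equal(sum(out$samples), sum(diff(codes) != 0))
})

test_that("quality rule excludes only when a channel is bad for > 50% of sleep", {
  g <- generate_recording(small_synth_config(seed = 31, wake_fraction = 0))
  q <- assess_quality(g$recording, g$hypnogram)
  expect_true(q$include)
  expect_true(all(q$per_channel_bad_fraction < 0.05))

  zero_span <- function(g, frac) {
    n <- length(g$recording$channels$Thor$samples)
    g$recording$channels$Thor$samples[seq_len(floor(n * frac))] <- 0
    g
  }
  g60 <- zero_span(g, 0.6)
  expect_false(assess_quality(g60$recording, g60$hypnogram)$include)
  g50 <- zero_span(g, 0.5)
  q50 <- assess_quality(g50$recording, g50$hypnogram)
  expect_true(q50$include)  # the rule is strictly "more than 50%"
  expect_true(q50$per_channel_bad_fraction[["Thor"]] <= 0.5)
})

test_that("widening a zeroed sleep span never decreases the bad fraction", {
  g <- generate_recording(small_synth_config(seed = 32, wake_fraction = 0))
  fracs <- vapply(c(0.1, 0.3, 0.5, 0.7), function(f) {
    gg <- g
    n <- length(gg$recording$channels$Thor$samples)
    gg$recording$channels$Thor$samples[seq_len(floor(n * f))] <- 0
    assess_quality(gg$recording, gg$hypnogram)$per_channel_bad_fraction[["Thor"]]
  }, numeric(1))
  expect_true(all(diff(fracs) >= 0))
})

test_that("labels mark exactly the seconds intersecting events", {
  hyp <- hypnogram(rep("N2", 2))
  lab <- make_labels(event_list(10, 13), hyp, 60)
  expect_equal(which(lab$labels_1hz == 1) - 1, c(10, 11, 12))
  expect_true(all(make_labels(event_list(), hyp, 60)$labels_1hz == 0))
  ov <- data.frame(onset = c(1, 2), offset = c(3, 4))
  class(ov) <- c("event_list", "data.frame")
  expect_error(make_labels(ov, hyp, 60), "overlap")
})

test_that("labels agree with a brute-force per-second intersection oracle", {
  set.seed(3)
  hyp <- hypnogram(sample(c("W", "N2"), 10, TRUE))
  for (i in 1:100) {
    ev <- random_event_list(sample(0:6, 1), horizon = 300)
    lab <- make_labels(ev, hyp, 300)$labels_1hz
    oracle <- vapply(0:299, function(t) {
      any(ev$onset < t + 1 & ev$offset > t)
    }, logical(1))
    expect_identical(lab, as.numeric(oracle))
  }
})

test_that("preprocessed continuous channels have median 0 and unit IQR", {
  g <- generate_recording(small_synth_config(seed = 33))
  pr <- preprocess_record(g$recording, g$hypnogram, g$events)
  for (nm in c("Thor", "DHR", "Snore")) {
    expect_lt(abs(median(pr$x[, nm])), 1e-6)
    expect_lt(abs(IQR(pr$x[, nm]) - 1), 1e-6)
  }
  expect_true(all(pr$x[, "WS"] %in% c(0, 1)))
  expect_equal(length(pr$labels_1hz), floor(g$recording$duration_s))
  expect_equal(nrow(pr$x), 4 * floor(g$recording$duration_s))
})
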