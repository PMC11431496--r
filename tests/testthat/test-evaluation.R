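test_that("the overlap criterion uses a strict inequality at omega_min", {
  crit <- match_criterion(0.5)
  # |G n D| / |G| = 6/10 = 0.6 > 0.5 -> matched
  m <- match_events(event_list(10, 20), event_list(14, 22), crit)
  expect_equal(c(m$tp, m$fp, m$fn), c(1, 0, 0))
  # ratio exactly 0.5 -> NOT matched
  m2 <- match_events(event_list(10, 20), event_list(15, 25), crit)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0, 1, 1))
  expect_error(match_criterion(0), "in \\(0, 1\\)")
})

test_that("matching equals the brute-force all-pairs oracle on random pairs", {
  set.seed(20)
  for (i in 1:300) {
    gt <- random_event_list(sample(0:12, 1), horizon = 500)
    det <- random_event_list(sample(0:12, 1), horizon = 500)
    ours <- match_events(gt, det)
    ref <- brute_force_match(gt, det)
    expect_equal(ours$tp, ref$tp)
    expect_equal(ours$fp, ref$fp)
    expect_equal(ours$fn, ref$fn)
    expect_equal(ours$gt_matched, ref$gt_matched)
  }
})

test_that("a detection spanning two ground truths counts once but credits both", {
  gt <- event_list(c(10, 20), c(14, 26))
  det <- event_list(8, 30)
  m <- match_events(gt, det)
  expect_equal(m$tp, 1)
  expect_equal(m$gt_matched, 2)
  expect_equal(m$recall, 1)
  expect_equal(m$precision, 1)
})

test_that("event recall is monotone non-decreasing as omega_min decreases", {
  set.seed(21)
  gt <- random_event_list(10, horizon = 400)
  det <- random_event_list(12, horizon = 400)
  recalls <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), function(om) {
    match_events(gt, det, match_criterion(om))$recall
  }, numeric(1))
  expect_true(all(diff(recalls) >= 0))
})

test_that("wake masking drops majority-wake events and keeps the rest intact", {
  mask <- c(rep(1, 30), rep(0, 30))  # sleep then wake
  ev <- event_list(c(5, 27, 40), c(10, 32, 45))
  out <- mask_wake(ev, mask)
  # wholly-sleep event kept, wholly-wake removed, 40%-wake event kept
  expect_equal(out$onset, c(5, 27))
  expect_equal(out$offset, c(10, 32))
})

test_that("pointwise metrics match independent confusion counting", {
  expect_equal(pointwise_metrics(c(1, 0, 1), c(1, 0, 1))$f1, 1)
  inv <- pointwise_metrics(c(0, 1, 0), c(1, 0, 1))
  expect_equal(c(inv$precision, inv$recall), c(0, 0))
  set.seed(22)
  pred <- rbinom(1e4, 1, 0.3)
  truth <- rbinom(1e4, 1, 0.2)
  mask <- rbinom(1e4, 1, 0.8)
  r <- pointwise_metrics(pred, truth, mask)
  k <- mask == 1
  tp <- sum(pred[k] & truth[k]); fp <- sum(pred[k] & !truth[k])
  fn <- sum(!pred[k] & truth[k])
  expect_equal(r$precision, tp / (tp + fp))
  expect_equal(r$recall, tp / (tp + fn))
  expect_equal(r$f1, 2 * r$precision * r$recall / (r$precision + r$recall))
})

test_that("recordwise summaries are the arithmetic mean/sd of per-record scores", {
  gt <- event_list(c(0, 20), c(5, 26))
  recs <- list(
    list(gt = gt, det = gt),                      # f1 = 1
    list(gt = gt, det = event_list(0, 5)),        # recall 0.5, precision 1
    list(gt = event_list(), det = event_list(0, 4))  # excluded: no gt
  )
  rw <- recordwise_metrics(recs)
  expect_equal(rw$n_excluded, 1)
  f1s <- c(1, 2 * 0.5 / 1.5)
  expect_equal(rw$summary$mean[rw$summary$metric == "f1"], mean(f1s))
  expect_equal(rw$summary$sd[rw$summary$metric == "f1"], sd(f1s))
  identical_recs <- list(list(gt = gt, det = gt), list(gt = gt, det = gt))
  expect_equal(recordwise_metrics(identical_recs)$summary$sd, rep(0, 3))
})

test_that("bootstrap paired test separates shifted pairs and not identical ones", {
  set.seed(23)
  a <- runif(30)
  same <- bootstrap_paired_test(a, a, n_boot = 1000, seed = 1)
  expect_true(same$flagged)
  expect_equal(same$p_value, 1)
  near <- bootstrap_paired_test(a + rnorm(30, 0, 1e-6), a, n_boot = 1000,
                                seed = 1)
  expect_gt(near$p_value, 0.2)
  shifted <- bootstrap_paired_test(a + 0.5 + rnorm(30, 0, 0.05), a,
                                   n_boot = 2000, seed = 1)
  expect_lt(shifted$p_value, 0.01)
})

test_that("bootstrap test type-I error is calibrated near alpha = 0.05", {
  set.seed(24)
  rejections <- vapply(1:1000, function(i) {
    a <- rnorm(20)
    b <- rnorm(20)
    bootstrap_paired_test(a, b, n_boot = 400, seed = i)$p_value <= 0.05
  }, logical(1))
  rate <- mean(rejections)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("Holm step-down matches the hand-computed decisions", {
  # 0.01 <= 0.05/3; 0.03 > 0.05/2 stops the step-down
  out <- holm_bonferroni(c(0.01, 0.03, 0.04), alpha = 0.05)
  expect_equal(out$reject, c(TRUE, FALSE, FALSE))
  expect_equal(holm_bonferroni(rep(1, 5))$reject, rep(FALSE, 5))
  expect_equal(holm_bonferroni(0.04, alpha = 0.05)$reject, TRUE)
  expect_equal(holm_bonferroni(numeric(0))$reject, logical(0))
})

test_that("relative confusion cells sum to the ground-truth count", {
  set.seed(25)
  gt <- lapply(1:5, function(i) random_event_list(sample(2:8, 1), 300))
  det_a <- lapply(1:5, function(i) random_event_list(sample(2:8, 1), 300))
  det_b <- lapply(1:5, function(i) random_event_list(sample(2:8, 1), 300))
  cm <- relative_confusion(gt, det_a, det_b)
  expect_equal(sum(cm), sum(vapply(gt, nrow, numeric(1))))
  # per-event brute-force classification oracle
  both <- only_a <- only_b <- neither <- 0
  for (r in 1:5) {
    for (i in seq_len(nrow(gt[[r]]))) {
      g1 <- event_list(gt[[r]]$onset[i], gt[[r]]$offset[i])
      a <- brute_force_match(g1, det_a[[r]])$gt_matched == 1
      b <- brute_force_match(g1, det_b[[r]])$gt_matched == 1
      if (a && b) both <- both + 1
      else if (a) only_a <- only_a + 1
      else if (b) only_b <- only_b + 1
      else neither <- neither + 1
    }
  }
  expect_equal(as.numeric(cm), as.numeric(c(both, only_b, only_a, neither)))
  # identical detectors have empty off-diagonal
  cm_same <- relative_confusion(gt, det_a, det_a)
  expect_equal(cm_same[1, 2] + cm_same[2, 1], 0)
  # empty B: only-A column equals A hits
  empties <- lapply(1:5, function(i) event_list())
  cm_eb <- relative_confusion(gt, det_a, empties)
  expect_equal(cm_eb[1, 1], 0)
  expect_equal(cm_eb[1, 2], sum(vapply(seq_along(gt), function(r) {
    brute_force_match(gt[[r]], det_a[[r]])$gt_matched
  }, numeric(1))))
})

test_that("arousal index arithmetic", {
  expect_equal(arousal_index(random_event_list(0), 8), 0)
  ev <- event_list(seq(0, 390, 10), seq(4, 394, 10))
  expect_equal(arousal_index(ev, 8), 5)
  expect_error(arousal_index(ev, 0), "positive")
})

test_that("Bland-Altman limits equal mean +/- 1.96 sd of the bias", {
  set.seed(26)
  true_ari <- runif(20, 5, 30)
  perfect <- bland_altman(true_ari, true_ari)
  expect_equal(perfect$mean_bias, 0)
  expect_equal(perfect$loa_lower, 0)
  expect_equal(perfect$pearson_r, 1)
  shift <- bland_altman(true_ari, true_ari + 2)
  expect_equal(shift$mean_bias, 2)
  expect_equal(shift$sd_bias, 0)
  est <- true_ari + rnorm(20, 1, 2)
  ba <- bland_altman(true_ari, est)
  d <- est - true_ari
  expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d))
  expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d))
  expect_equal(ba$pearson_r, cor(true_ari, est))
  expect_error(bland_altman(1, 2), "at least 2")
})
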