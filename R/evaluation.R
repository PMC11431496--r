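#' Event-matching criterion
#'
#' A detection matches a ground-truth event when it covers strictly more
#' than `omega_min` of it: `|G intersect D| / |G| > omega_min`.
#'
#' @param omega_min Minimum ground-truth coverage proportion in (0, 1);
#'   default 0.5.
#' @return A `match_criterion` list.
#' @export
match_criterion <- function(omega_min = 0.5) {
  if (omega_min <= 0 || omega_min >= 1) stop("omega_min must be in (0, 1)")
  structure(list(omega_min = omega_min), class = "match_criterion")
}

#' Remove events that fall in wakefulness
#'
#' Events whose majority of covered seconds lie in wake epochs are removed;
#' all others are kept intact (a partially wake-overlapping event with at
#' least half its seconds in sleep survives).
#'
#' @param events An `event_list`.
#' @param sleep_mask_1hz Per-second sleep indicator (entry `t+1` covers
#'   second `[t, t+1)`).
#' @return The filtered `event_list`.
#' @export
mask_wake <- function(events, sleep_mask_1hz) {
  if (nrow(events) == 0L) return(events)
  keep <- vapply(seq_len(nrow(events)), function(i) {
    ts <- floor(events$onset[i]):(ceiling(events$offset[i]) - 1)
    ts <- ts[events$onset[i] < ts + 1 & events$offset[i] > ts & ts >= 0 &
               ts < length(sleep_mask_1hz)]
    if (length(ts) == 0L) return(TRUE)
    mean(sleep_mask_1hz[ts + 1L] == 1) >= 0.5
  }, logical(1))
  out <- events[keep, , drop = FALSE]
  class(out) <- c("event_list", "data.frame")
  out
}

#' Match detections against ground-truth events
#'
#' A ground-truth event `G` counts as found iff some detection covers
#' strictly more than `omega_min` of it.  A detection is a true positive if
#' it matches at least one ground-truth event (a single detection spanning
#' several ground-truth events counts once as a true positive but credits
#' each spanned event as found); detections matching none are false
#' positives; unmatched ground-truth events are false negatives.
#'
#' @param gt Ground-truth `event_list`.
#' @param det Detected `event_list`.
#' @param crit A [match_criterion()].
#' @return An `event_report` list: counts `tp`, `fp`, `fn`, `n_gt`,
#'   `n_det`, `gt_matched`, and `precision` (`tp / n_det`), `recall`
#'   (`gt_matched / n_gt`), `f1`; ratios are 0 with `flagged = TRUE` when a
#'   denominator is 0.
#' @export
match_events <- function(gt, det, crit = match_criterion()) {
  validate_event_list(gt)
  validate_event_list(det)
  n_gt <- nrow(gt); n_det <- nrow(det)
  gt_hit <- logical(n_gt)
  det_hit <- logical(n_det)
  if (n_gt > 0L && n_det > 0L) {
    j0 <- 1L
    for (i in seq_len(n_gt)) {
      g_on <- gt$onset[i]; g_off <- gt$offset[i]
      glen <- g_off - g_on
      # advance past detections that end before this ground truth starts
      while (j0 <= n_det && det$offset[j0] <= g_on) j0 <- j0 + 1L
      j <- j0
      while (j <= n_det && det$onset[j] < g_off) {
        ov <- min(g_off, det$offset[j]) - max(g_on, det$onset[j])
        if (ov / glen > crit$omega_min) {
          gt_hit[i] <- TRUE
          det_hit[j] <- TRUE
        }
        j <- j + 1L
      }
    }
  }
  tp <- sum(det_hit)
  fp <- n_det - tp
  fn <- sum(!gt_hit)
  gt_matched <- n_gt - fn
  flagged <- (n_det == 0L) || (n_gt == 0L)
  precision <- if (n_det > 0L) tp / n_det else 0
  recall <- if (n_gt > 0L) gt_matched / n_gt else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  structure(list(tp = tp, fp = fp, fn = fn, n_gt = n_gt, n_det = n_det,
                 gt_matched = gt_matched, precision = precision,
                 recall = recall, f1 = f1, flagged = flagged),
            class = "event_report")
}

#' Pointwise metrics over concatenated sleep-time seconds
#'
#' Precision, recall and F1 of per-second binary predictions against
#' labels, restricted to sleep seconds; when `probs` is supplied, AUPRC
#' and AUROC of the probability scores are added.
#'
#' @param pred_labels Binary per-second predictions (concatenated records).
#' @param true_labels Binary per-second ground truth.
#' @param sleep_mask Per-second sleep indicator; only seconds with mask 1
#'   enter the metrics.  Defaults to all seconds.
#' @param probs Optional per-second probabilities for the curve areas.
#' @return A `pointwise_report` list: `precision`, `recall`, `f1`,
#'   optionally `auprc`/`auroc`, plus a `flagged` marker when recall is
#'   undefined (no positive seconds).
#' @export
pointwise_metrics <- function(pred_labels, true_labels,
                              sleep_mask = NULL, probs = NULL) {
  stopifnot(length(pred_labels) == length(true_labels))
  keep <- if (is.null(sleep_mask)) rep(TRUE, length(true_labels)) else
    sleep_mask[seq_along(true_labels)] == 1
  p <- pred_labels[keep]; y <- true_labels[keep]
  tp <- sum(p == 1 & y == 1)
  fp <- sum(p == 1 & y == 0)
  fn <- sum(p == 0 & y == 1)
  flagged <- (tp + fn) == 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  rep_ <- list(precision = precision, recall = recall, f1 = f1,
               tp = tp, fp = fp, fn = fn, flagged = flagged)
  if (!is.null(probs)) {
    sc <- probs[keep]
    rep_$auprc <- if (sum(y) > 0) auprc(y, sc) else NA_real_
    rep_$auroc <- if (sum(y) > 0 && sum(y == 0) > 0) auroc(y, sc) else
      NA_real_
  }
  structure(rep_, class = "pointwise_report")
}

#' Recordwise event-based metrics
#'
#' Computes an event report per record and summarizes each metric by its
#' mean and standard deviation.  Records without ground-truth events are
#' flagged and excluded from the summaries.
#'
#' @param per_record_events List of `list(gt = , det = )` pairs.
#' @param crit A [match_criterion()].
#' @return A `recordwise_report`: `per_record` (list of `event_report`s),
#'   `summary` (data frame with mean and sd of precision, recall, f1),
#'   `n_excluded`.
#' @export
recordwise_metrics <- function(per_record_events, crit = match_criterion()) {
  stopifnot(length(per_record_events) >= 1L)
  reports <- lapply(per_record_events, function(pr) {
    match_events(pr$gt, pr$det, crit)
  })
  usable <- vapply(reports, function(r) r$n_gt > 0L, logical(1))
  metr <- function(field) {
    vapply(reports[usable], function(r) r[[field]], numeric(1))
  }
  summary <- data.frame(
    metric = c("precision", "recall", "f1"),
    mean = c(mean(metr("precision")), mean(metr("recall")), mean(metr("f1"))),
    sd = c(stats::sd(metr("precision")), stats::sd(metr("recall")),
           stats::sd(metr("f1")))
  )
  structure(list(per_record = reports, summary = summary,
                 n_excluded = sum(!usable)),
            class = "recordwise_report")
}

#' Bootstrap paired t-test
#'
#' Resamples the mean-centred paired differences with replacement,
#' recomputes the t-statistic for each bootstrap sample, and reports the
#' two-sided p-value as the proportion of bootstrap t-statistics at least
#' as extreme as the observed one.
#'
#' @param metric_a,metric_b Paired per-record metric vectors.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return A list: `p_value`, `t_obs`, `mean_diff`, `flagged` (`TRUE` when
#'   the differences have zero variance, in which case `p_value` is 1).
#' @export
bootstrap_paired_test <- function(metric_a, metric_b, n_boot = 10000L,
                                  seed = 1L) {
  stopifnot(length(metric_a) == length(metric_b), length(metric_a) >= 2L)
  d <- metric_a - metric_b
  n <- length(d)
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    return(list(p_value = 1, t_obs = 0, mean_diff = mean(d), flagged = TRUE))
  }
  t_obs <- mean(d) / (sd_d / sqrt(n))
  dc <- d - mean(d)
  t_boot <- with_seed(seed, {
    idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
    samp <- matrix(dc[idx], n, n_boot)
    mu <- colMeans(samp)
    s <- sqrt((colSums(samp^2) - n * mu^2) / (n - 1))
    ifelse(s == 0, 0, mu / (s / sqrt(n)))
  })
  p <- mean(abs(t_boot) >= abs(t_obs))
  list(p_value = p, t_obs = t_obs, mean_diff = mean(d), flagged = FALSE)
}

#' Holm step-down multiple-comparison decisions
#'
#' Sorts the p-values ascending and rejects while
#' `p_(k) <= alpha / (m - k + 1)`, stopping at the first failure.
#'
#' @param p_values Vector of p-values in `[0, 1]`.
#' @param alpha Family-wise error level.
#' @return A list with `reject` (logical, in input order) and `adjusted_p`
#'   (Holm-adjusted p-values).
#' @export
holm_bonferroni <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) {
    return(list(reject = logical(0), adjusted_p = numeric(0)))
  }
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "holm")
  list(reject = adj <= alpha, adjusted_p = adj)
}

#' Relative confusion matrix between two detectors
#'
#' Classifies every ground-truth event by which of two detectors found it
#' (using the overlap criterion per detector): both, only A, only B, or
#' neither.  The four cells sum to the total number of ground-truth
#' events.
#'
#' @param gt List of ground-truth `event_list`s (one per record).
#' @param det_a,det_b Lists of detections from detectors A and B.
#' @param crit A [match_criterion()].
#' @return A 2x2 matrix with rows `A detected`/`A missed` and columns
#'   `B detected`/`B missed`.
#' @export
relative_confusion <- function(gt, det_a, det_b, crit = match_criterion()) {
  stopifnot(length(gt) == length(det_a), length(gt) == length(det_b))
  cells <- c(both = 0L, only_a = 0L, only_b = 0L, neither = 0L)
  hit_by <- function(g, d) {
    if (nrow(g) == 0L) return(logical(0))
    vapply(seq_len(nrow(g)), function(i) {
      if (nrow(d) == 0L) return(FALSE)
      ov <- pmin(g$offset[i], d$offset) - pmax(g$onset[i], d$onset)
      any(ov / (g$offset[i] - g$onset[i]) > crit$omega_min)
    }, logical(1))
  }
  for (r in seq_along(gt)) {
    a <- hit_by(gt[[r]], det_a[[r]])
    b <- hit_by(gt[[r]], det_b[[r]])
    cells["both"] <- cells["both"] + sum(a & b)
    cells["only_a"] <- cells["only_a"] + sum(a & !b)
    cells["only_b"] <- cells["only_b"] + sum(!a & b)
    cells["neither"] <- cells["neither"] + sum(!a & !b)
  }
  matrix(c(cells["both"], cells["only_a"], cells["only_b"],
           cells["neither"]), 2L, 2L, byrow = TRUE,
         dimnames = list(c("A detected", "A missed"),
                         c("B detected", "B missed")))
}

#' Arousal index: events per hour of sleep
#'
#' @param events An `event_list`.
#' @param total_sleep_time_h Total sleep time in hours (> 0).
#' @return Events per hour of sleep.
#' @export
arousal_index <- function(events, total_sleep_time_h) {
  if (total_sleep_time_h <= 0) stop("total sleep time must be positive")
  nrow(events) / total_sleep_time_h
}

#' Bland-Altman agreement between true and estimated arousal indexes
#'
#' Per-record bias is `estimated - true`; the report carries the mean
#' bias, the 95% limits of agreement (mean +/- 1.96 sd) and the Pearson
#' correlation between the paired indexes.
#'
#' @param true_ari,est_ari Paired per-record arousal indexes (n >= 2).
#' @return An `ari_report` list: `bias` (per record), `mean_bias`,
#'   `loa_lower`, `loa_upper`, `sd_bias`, `pearson_r`.
#' @export
bland_altman <- function(true_ari, est_ari) {
  stopifnot(length(true_ari) == length(est_ari))
  if (length(true_ari) < 2L) stop("Bland-Altman needs at least 2 records")
  bias <- est_ari - true_ari
  m <- mean(bias)
  s <- stats::sd(bias)
  r <- if (stats::sd(true_ari) == 0 || stats::sd(est_ari) == 0) {
    if (s == 0) 1 else NA_real_
  } else {
    stats::cor(true_ari, est_ari)
  }
  structure(list(bias = bias, mean_bias = m, sd_bias = s,
                 loa_lower = m - 1.96 * s, loa_upper = m + 1.96 * s,
                 pearson_r = r),
            class = "ari_report")
}
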