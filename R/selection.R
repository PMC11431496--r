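#' @title Greedy incremental signal selection
#' @name hstarousal-selection
#' @description
#' The selection driver searches the candidate signal pool (`Thor`, `DHR`,
#' `Snore`, `Pos`, `Pos_chg`, `WS`) for combinations that improve
#' EEG-free arousal detection.  Round I trains single-signal models on
#' `DHR`, `Thor` and `Snore` only (position and wake/sleep make no sense
#' alone); each later round augments the best previous combination with
#' every unused candidate, trains one model per candidate combination,
#' ranks by mean recordwise event-based F1, and advances the winner.
NULL

SIGNAL_POOL <- c("Thor", "DHR", "Snore", "Pos", "Pos_chg", "WS")
ROUND_ONE_CANDIDATES <- c("DHR", "Thor", "Snore")

combo_key <- function(signals) paste(sort(signals), collapse = "+")

#' Initialize a selection state
#'
#' @param signal_pool Candidate signal names.
#' @param round_one_candidates Signals allowed as single inputs in round I.
#' @return A `selection_state` list.
#' @export
selection_state <- function(signal_pool = SIGNAL_POOL,
                            round_one_candidates = ROUND_ONE_CANDIDATES) {
  stopifnot(all(round_one_candidates %in% signal_pool))
  structure(list(round_index = 0L, signal_pool = signal_pool,
                 round_one_candidates = round_one_candidates,
                 best_combo = character(0), best_score = -Inf,
                 evaluated = list(), selection_path = list(),
                 round_winners = list()),
            class = "selection_state")
}

#' Candidate combinations for the next round
#'
#' Round I proposes the single-signal candidates; later rounds propose the
#' best previous combination augmented by each unused pool signal.
#' Combinations already evaluated in this run are never proposed again.
#'
#' @param state A `selection_state`.
#' @return List of character vectors (possibly empty, signalling
#'   termination).
#' @export
propose_candidates <- function(state) {
  if (state$round_index == 0L) {
    cands <- lapply(state$round_one_candidates, identity)
  } else {
    unused <- setdiff(state$signal_pool, state$best_combo)
    cands <- lapply(unused, function(s) c(state$best_combo, s))
  }
  cands[!vapply(cands, function(cc) combo_key(cc) %in% names(state$evaluated),
                logical(1))]
}

#' Candidate triples for the multi-advance third round
#'
#' When several round-II pairs are flagged as jointly advancing, round III
#' explores the round-I winner combined with every 2-subset of the union
#' of the advancing pairs' partner signals plus `Pos` (with `Pos_chg`
#' excluded, mirroring the published schedule).
#'
#' @param state A `selection_state` after round II.
#' @param partners Character vector of partner signals of the advancing
#'   pairs (the signal each pair added to the round-I winner).
#' @return List of candidate combinations (character vectors).
#' @export
replicate_round3_schedule <- function(state, partners) {
  if (length(partners) == 0L) stop("empty partner set")
  base <- state$selection_path[[1L]]$combo
  partners <- setdiff(union(partners, "Pos"), c("Pos_chg", base))
  if (length(partners) < 2L) {
    return(propose_candidates(state))
  }
  pairs <- utils::combn(sort(partners), 2L, simplify = FALSE)
  lapply(pairs, function(pr) c(base, pr))
}

#' Run one selection round
#'
#' Trains/evaluates one model per candidate combination via `fit_fn` and
#' ranks the candidates by their score (mean recordwise event-based F1 in
#' the full pipeline).  A candidate whose fit fails is recorded and
#' skipped.  Candidate order does not affect the result: the winner is the
#' score maximizer, with ties broken by combination key.
#'
#' @param candidates List of character vectors of signal names.
#' @param fit_fn Function `(signals, seed)` returning a list with at least
#'   `score` (numeric); anything else it returns is kept in the report.
#' @param seed Master seed; each candidate gets a seed derived from it and
#'   the combination key, so results do not depend on evaluation order.
#' @return A list: `best` (character vector), `best_score`, `reports`
#'   (named by combination key), `failed` (character vector of keys).
#' @export
run_round <- function(candidates, fit_fn, seed = 1L) {
  stopifnot(length(candidates) >= 1L)
  keys <- vapply(candidates, combo_key, character(1))
  o <- order(keys)
  candidates <- candidates[o]
  keys <- keys[o]
  reports <- list()
  failed <- character(0)
  for (i in seq_along(candidates)) {
    res <- tryCatch(
      fit_fn(candidates[[i]], derive_seed(seed, keys[i])),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failed <- c(failed, keys[i])
      next
    }
    reports[[keys[i]]] <- res
  }
  if (length(reports) == 0L) stop("all candidates failed in this round")
  scores <- vapply(reports, function(r) r$score, numeric(1))
  best_key <- names(scores)[which.max(scores)]
  best <- candidates[[match(best_key, keys)]]
  list(best = best, best_score = max(scores), reports = reports,
       failed = failed)
}

#' Run the full incremental selection
#'
#' Executes rounds until the candidate pool is exhausted (or, with
#' `stop_on_no_improvement`, until a round fails to beat the incumbent
#' score).  Two schedules are available:
#'
#' * `"greedy"` — pure greedy forward selection: round I singles, then the
#'   best combination plus each unused signal, every round.
#' * `"published"` — the published 16-combination path: round I singles
#'   (3 candidates); round II pairs (5); round III multi-advance triples
#'   via [replicate_round3_schedule()], where the advancing pairs are
#'   those that beat the round-I best score (6 candidates); rounds IV and
#'   V extend the incumbent with the remaining non-`Pos_chg` signals one
#'   per round, ordered by their round-II pair score (1 candidate each).
#'
#' @param fit_fn As in [run_round()].
#' @param schedule `"greedy"` or `"published"`.
#' @param seed Master seed.
#' @param stop_on_no_improvement Stop when a round's best score does not
#'   exceed the previous best.
#' @param signal_pool,round_one_candidates Pool configuration.
#' @return The final `selection_state`, whose `selection_path` records the
#'   winning combination and score per round, `evaluated` every
#'   combination's report, and `n_evaluated` the total count.
#' @export
run_incremental <- function(fit_fn, schedule = c("greedy", "published"),
                            seed = 1L, stop_on_no_improvement = FALSE,
                            signal_pool = SIGNAL_POOL,
                            round_one_candidates = ROUND_ONE_CANDIDATES) {
  schedule <- match.arg(schedule)
  state <- selection_state(signal_pool, round_one_candidates)
  repeat {
    round_i <- state$round_index + 1L
    if (schedule == "published" && round_i == 3L && length(signal_pool) == 6L) {
      pair_scores <- vapply(state$round_winners[["2"]]$reports,
                            function(r) r$score, numeric(1))
      r1_best <- state$selection_path[[1L]]$score
      partners <- vapply(names(pair_scores)[pair_scores > r1_best],
                         function(k) {
                           setdiff(strsplit(k, "+", fixed = TRUE)[[1]],
                                   state$selection_path[[1L]]$combo)
                         }, character(1))
      if (length(partners) == 0L) {
        best_pair <- names(pair_scores)[which.max(pair_scores)]
        partners <- setdiff(strsplit(best_pair, "+", fixed = TRUE)[[1]],
                            state$selection_path[[1L]]$combo)
      }
      cands <- replicate_round3_schedule(state, partners)
    } else if (schedule == "published" && round_i >= 4L &&
               length(signal_pool) == 6L) {
      remaining <- setdiff(setdiff(signal_pool, "Pos_chg"), state$best_combo)
      if (length(remaining) == 0L) break
      pair_scores <- vapply(state$round_winners[["2"]]$reports,
                            function(r) r$score, numeric(1))
      pair_partner <- vapply(names(pair_scores), function(k) {
        setdiff(strsplit(k, "+", fixed = TRUE)[[1]],
                state$selection_path[[1L]]$combo)
      }, character(1))
      pr <- pair_scores[match(remaining, pair_partner)]
      nxt <- remaining[order(-pr)][1L]
      cands <- list(c(state$best_combo, nxt))
    } else {
      cands <- propose_candidates(state)
    }
    cands <- cands[!vapply(cands, function(cc) {
      combo_key(cc) %in% names(state$evaluated)
    }, logical(1))]
    if (length(cands) == 0L) break
    rr <- run_round(cands, fit_fn, seed)
    state$evaluated <- c(state$evaluated, rr$reports)
    state$round_index <- round_i
    state$round_winners[[as.character(round_i)]] <- rr
    improved <- rr$best_score > state$best_score
    state$selection_path[[round_i]] <- list(combo = rr$best,
                                            score = rr$best_score)
    if (improved || round_i == 1L) {
      state$best_combo <- rr$best
      state$best_score <- rr$best_score
    } else if (stop_on_no_improvement) {
      break
    } else {
      # keep expanding from the round winner even without improvement
      state$best_combo <- rr$best
      state$best_score <- rr$best_score
    }
  }
  state$n_evaluated <- length(state$evaluated)
  state
}

#' Fit-and-score pipeline for one signal combination
#'
#' The default `fit_fn` for [run_incremental()]: builds a model for the
#' given channels, trains it on the training split, optimizes the decision
#' threshold on the validation split, postprocesses the test split and
#' scores mean recordwise event-based F1.
#'
#' @param datasets A list with `train`, `val`, `test` lists of
#'   `preprocessed_record`s.
#' @param model_args,train_args Named lists of overrides passed to
#'   [model_config()] / [train_config()].
#' @param config A [postprocess_config()].
#' @param crit A [match_criterion()].
#' @return A function `(signals, seed)` returning `score`, `threshold`,
#'   `recordwise` and the trained model.
#' @export
make_pipeline_fit_fn <- function(datasets, model_args = list(),
                                 train_args = list(),
                                 config = postprocess_config(),
                                 crit = match_criterion()) {
  force(datasets)
  function(signals, seed) {
    mc <- do.call(model_config,
                  c(list(n_input_channels = length(signals), seed = seed),
                    model_args))
    tc <- do.call(train_config, c(list(seed = seed), train_args))
    model <- build_model(mc)
    fit <- train(model, datasets$train, datasets$val, tc,
                 channels = signals)
    val_probs <- lapply(datasets$val, function(r) {
      predict_probs(fit$model, select_input(r, signals))
    })
    val_events <- lapply(datasets$val, function(r) {
      seconds_to_events(r$labels_1hz)
    })
    val_masks <- lapply(datasets$val, function(r) r$sleep_mask_1hz)
    thr <- optimize_threshold(val_probs, val_events, val_masks, config, crit)
    per_record <- lapply(datasets$test, function(r) {
      probs <- predict_probs(fit$model, select_input(r, signals))
      det <- discard_long_detections(postprocess(probs, thr, config))
      det <- mask_wake(det, r$sleep_mask_1hz)
      gt <- mask_wake(seconds_to_events(r$labels_1hz), r$sleep_mask_1hz)
      list(gt = gt, det = det)
    })
    rw <- recordwise_metrics(per_record, crit)
    list(score = rw$summary$mean[rw$summary$metric == "f1"],
         threshold = thr, recordwise = rw, model = fit$model,
         history = fit$history)
  }
}

#' Convert a per-second binary label vector to an event list
#'
#' Maximal runs of positive seconds become half-open events; the inverse of
#' label rasterization at 1 Hz.
#'
#' @param labels_1hz Binary per-second labels.
#' @return An `event_list`.
#' @export
seconds_to_events <- function(labels_1hz) {
  pos <- labels_1hz == 1
  if (!any(pos)) return(event_list())
  r <- rle(pos)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  event_list(starts[keep] - 1, ends[keep])
}
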