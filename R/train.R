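#' Training configuration
#'
#' Defaults follow the training recipe: per-second binary cross-entropy,
#' batches of 30 record streams advanced by truncated backpropagation
#' through time with a depth of 90 output seconds (360 input samples),
#' Adam (beta1 = 0.9, beta2 = 0.999, weight decay 1e-5), initial learning
#' rate 1e-4 reduced by a factor of 10 when validation AUPRC fails to
#' improve for four consecutive epochs, 30 epochs, and selection of the
#' epoch with the best validation AUPRC.
#'
#' @param batch_size Record streams per batch.
#' @param tbptt_depth Output seconds per truncated segment.
#' @param adam_beta1,adam_beta2 Adam moment decay rates.
#' @param weight_decay L2 penalty coefficient (the recipe's lambda).
#' @param lr_init Initial learning rate.
#' @param lr_factor Multiplicative learning-rate reduction on plateau.
#' @param lr_patience Consecutive non-improving epochs before reduction.
#' @param max_epochs Number of training epochs.
#' @param seed Seed controlling shuffling (and any other training
#'   randomness).
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 30L, tbptt_depth = 90L,
                         adam_beta1 = 0.9, adam_beta2 = 0.999,
                         weight_decay = 1e-5, lr_init = 1e-4,
                         lr_factor = 0.1, lr_patience = 4L,
                         max_epochs = 30L, seed = 1L) {
  structure(list(batch_size = as.integer(batch_size),
                 tbptt_depth = as.integer(tbptt_depth),
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 weight_decay = weight_decay, lr_init = lr_init,
                 lr_factor = lr_factor, lr_patience = as.integer(lr_patience),
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Area under the precision-recall curve
#'
#' Step-wise integration over all unique score thresholds (no
#' interpolation): walking the scores in decreasing order, the area is the
#' sum of recall increments times the precision at each step.
#'
#' @param labels Binary 0/1 vector.
#' @param scores Numeric scores, higher = more positive.
#' @return AUPRC in `[0, 1]`; error if no positive labels.
#' @export
auprc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  P <- sum(labels == 1)
  if (P == 0) stop("AUPRC is undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  tp <- cumsum(lab == 1)
  fp <- cumsum(lab == 0)
  last <- !duplicated(sc, fromLast = TRUE)  # last index of each threshold
  tp <- tp[last]; fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Area under the ROC curve (rank statistic)
#'
#' Computed as the Wilcoxon-Mann-Whitney statistic: the probability that a
#' random positive outranks a random negative (ties count 1/2).
#'
#' @inheritParams auprc
#' @return AUROC in `[0, 1]`; error unless both classes are present.
#' @export
auroc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  nP <- sum(labels == 1)
  nN <- sum(labels == 0)
  if (nP == 0 || nN == 0) stop("AUROC needs both classes present")
  r <- rank(scores)
  (sum(r[labels == 1]) - nP * (nP + 1) / 2) / (nP * nN)
}

select_input <- function(rec, channels = NULL) {
  if (is.null(channels)) rec$x else {
    missing_ch <- setdiff(channels, colnames(rec$x))
    if (length(missing_ch) > 0L) {
      stop("channels not present in record: ",
           paste(missing_ch, collapse = ", "))
    }
    rec$x[, channels, drop = FALSE]
  }
}

#' Validation AUPRC of a model over preprocessed records
#'
#' Concatenates per-second predictions of all records, restricted to sleep
#' seconds, and computes the area under the precision-recall curve.
#'
#' @param model An `arousal_model`.
#' @param val_records List of `preprocessed_record`s.
#' @param channels Optional channel subset (columns of `x`) to feed.
#' @return Validation AUPRC; error if the (sleep-masked) validation labels
#'   contain no positives.
#' @export
evaluate_epoch <- function(model, val_records, channels = NULL) {
  probs <- numeric(0)
  labels <- numeric(0)
  for (rec in val_records) {
    p <- predict_probs(model, select_input(rec, channels))
    keep <- rec$sleep_mask_1hz[seq_along(p)] == 1
    probs <- c(probs, p[keep])
    labels <- c(labels, rec$labels_1hz[seq_along(p)][keep])
  }
  if (sum(labels) == 0) {
    stop("validation AUPRC is undefined: no positive sleep-time labels")
  }
  auprc(labels, probs)
}

bce_loss <- function(probs, y, mask) {
  eps <- 1e-12
  l <- -(y * log(probs + eps) + (1 - y) * log(1 - probs + eps))
  sum(l * mask) / max(sum(mask), 1)
}

# Loss and gradients for a full (un-truncated) sequence on one record;
# used by gradient checks and as the short-record reference for TBPTT.
model_loss_grads <- function(model, x, y, training = TRUE) {
  X <- array(x, c(1L, nrow(x), ncol(x)))
  out <- model_fwd(model, X, training = training, keep_cache = TRUE)
  probs <- sigmoid(out$logits)
  Tn <- ncol(out$logits)
  stopifnot(length(y) == Tn)
  mask <- matrix(1, 1L, Tn)
  loss <- bce_loss(probs, matrix(y, 1L), mask)
  dlogits <- (probs - matrix(y, 1L)) / Tn
  grads <- model_bwd(out$model, out$caches, dlogits)
  list(loss = loss, grads = grads, model = out$model)
}

#' Train the detector
#'
#' Records are processed as parallel streams: each batch takes up to
#' `batch_size` records, advances them in lockstep through truncated
#' segments of `tbptt_depth` output seconds (4x input samples), carries the
#' LSTM state across segments within a record and resets it between
#' records.  Records shorter than the longest in their batch are masked out
#' of the loss, not padded into it.  The loss is the mean per-second binary
#' cross-entropy over (unmasked) sequence seconds.
#'
#' @param model An `arousal_model` built with the matching channel count.
#' @param train_records,val_records Lists of `preprocessed_record`s.
#' @param config A [train_config()].
#' @param channels Optional channel subset to feed (columns of each
#'   record's `x`).
#' @param verbose Print one line per epoch.
#' @return A list: `model` (checkpoint of the best-validation-AUPRC epoch),
#'   `history` (data frame of epoch, train_loss, val_auprc, lr),
#'   `best_epoch`, and `final_model` (state after the last epoch).
#' @export
train <- function(model, train_records, val_records, config = train_config(),
                  channels = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "train_config"))
  if (length(train_records) == 0L) stop("empty training set")
  xs <- lapply(train_records, select_input, channels = channels)
  ys <- lapply(train_records, function(r) r$labels_1hz)
  lr <- config$lr_init
  opt <- adam_init(model$params)
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_auprc = numeric(0), lr = numeric(0))
  best <- list(auprc = -Inf, epoch = NA_integer_, params = NULL, bn = NULL)
  since_improve <- 0L
  seg_secs <- config$tbptt_depth
  seg_len <- 4L * seg_secs

  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_seed(config$seed, paste0("epoch-", epoch)),
                     sample.int(length(xs)))
    loss_num <- 0; loss_den <- 0
    for (bstart in seq(1L, length(ord), by = config$batch_size)) {
      idx <- ord[bstart:min(bstart + config$batch_size - 1L, length(ord))]
      B <- length(idx)
      T_secs <- vapply(idx, function(i) length(ys[[i]]), integer(1))
      maxT <- max(T_secs)
      C <- ncol(xs[[idx[1]]])
      Xb <- array(0, c(B, 4L * maxT, C))
      Yb <- matrix(0, B, maxT)
      Mb <- matrix(0, B, maxT)
      for (j in seq_len(B)) {
        i <- idx[j]
        Xb[j, seq_len(4L * T_secs[j]), ] <- xs[[i]][seq_len(4L * T_secs[j]), ]
        Yb[j, seq_len(T_secs[j])] <- ys[[i]]
        Mb[j, seq_len(T_secs[j])] <- 1
      }
      state <- zero_state(model, B)
      n_seg <- ceiling(maxT / seg_secs)
      for (s in seq_len(n_seg)) {
        sec_idx <- ((s - 1L) * seg_secs + 1L):min(s * seg_secs, maxT)
        smp_idx <- ((s - 1L) * seg_len + 1L):(4L * max(sec_idx))
        Xseg <- Xb[, smp_idx, , drop = FALSE]
        Yseg <- Yb[, sec_idx, drop = FALSE]
        Mseg <- Mb[, sec_idx, drop = FALSE]
        m_sum <- sum(Mseg)
        if (m_sum == 0) break
        out <- model_fwd(model, Xseg, training = TRUE, state = state,
                         keep_cache = TRUE)
        model <- out$model
        state <- out$state
        probs <- sigmoid(out$logits)
        loss_num <- loss_num + sum(Mseg * (-(Yseg * log(probs + 1e-12) +
          (1 - Yseg) * log(1 - probs + 1e-12))))
        loss_den <- loss_den + m_sum
        dlogits <- Mseg * (probs - Yseg) / m_sum
        grads <- model_bwd(model, out$caches, dlogits)
        grads$dX <- NULL
        step <- adam_step(model$params, grads, opt, lr,
                          beta1 = config$adam_beta1,
                          beta2 = config$adam_beta2,
                          weight_decay = config$weight_decay)
        model$params <- step$params
        opt <- step$state
      }
    }
    val <- evaluate_epoch(model, val_records, channels)
    history <- rbind(history,
                     data.frame(epoch = epoch,
                                train_loss = loss_num / max(loss_den, 1),
                                val_auprc = val, lr = lr))
    if (verbose) {
      message(sprintf("epoch %2d  loss %.5f  val AUPRC %.4f  lr %g",
                      epoch, loss_num / max(loss_den, 1), val, lr))
    }
    if (val > best$auprc) {
      best <- list(auprc = val, epoch = epoch, params = model$params,
                   bn = model$bn)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
      if (since_improve >= config$lr_patience) {
        lr <- lr * config$lr_factor
        since_improve <- 0L
      }
    }
  }
  best_model <- model
  best_model$params <- best$params
  best_model$bn <- best$bn
  list(model = best_model, history = history, best_epoch = best$epoch,
       final_model = model)
}
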