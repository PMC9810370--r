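# Shared training loop: Adam on minibatch MAE with per-family learning-rate
# schedules, plateau handling with best-checkpoint restore, and evaluation
# helpers.

#' Training schedule presets
#'
#' Family defaults: the recurrent model trains 70 epochs on minibatches of
#' 16 at initial learning rate 0.1 decayed by 0.1 at epochs 20/40/60; the
#' WaveNet 30 epochs, batch 8, rate 1e-4 decayed at 10/20; the attention
#' model 40 epochs, batch 16, rate 0.1 decayed at 10/20/30. If validation
#' error fails to improve for more than `patience` epochs the best weights
#' are restored and the next decay fires early; the final model is always
#' the best-validation checkpoint. `small_cohort = TRUE` doubles the epoch
#' budget and shifts the decay epochs accordingly (the low-data regime).
#' Any field can be overridden for scaled-down experiments.
#'
#' @param family `"dcrnn"`, `"gwn"` or `"tatt"`
#' @param epochs,batch_size,lr,decay_epochs,decay_factor,patience,clip
#'   overrides of the family defaults; `clip` is a global gradient-norm
#'   bound (NULL disables clipping)
#' @param small_cohort use the doubled low-data schedule
#' @param seed integer seed driving minibatch shuffling and scheduled
#'   sampling
#' @return a `train_schedule`
#' @export
train_schedule <- function(family = c("dcrnn", "gwn", "tatt"),
                           epochs = NULL, batch_size = NULL, lr = NULL,
                           decay_epochs = NULL, decay_factor = 0.1,
                           patience = 10L, clip = NULL,
                           small_cohort = FALSE, seed = 1L) {
  family <- match.arg(family)
  def <- switch(family,
    dcrnn = list(epochs = 70L, batch_size = 16L, lr = 0.1,
                 decay_epochs = c(20L, 40L, 60L), clip = 5),
    gwn = list(epochs = 30L, batch_size = 8L, lr = 1e-4,
               decay_epochs = c(10L, 20L), clip = NULL),
    tatt = list(epochs = 40L, batch_size = 16L, lr = 0.1,
                decay_epochs = c(10L, 20L, 30L), clip = NULL))
  if (small_cohort) {
    def$epochs <- def$epochs * 2L
    def$decay_epochs <- def$decay_epochs * 2L
  }
  epochs <- as.integer(epochs %||% def$epochs)
  lr <- lr %||% def$lr
  stopifnot(epochs >= 1L, lr > 0, decay_factor > 0, decay_factor < 1)
  structure(list(
    family = family, epochs = epochs,
    batch_size = as.integer(batch_size %||% def$batch_size),
    lr = lr, decay_epochs = as.integer(decay_epochs %||% def$decay_epochs),
    decay_factor = decay_factor, patience = as.integer(patience),
    clip = if (is.null(clip)) def$clip else clip,
    seed = as.integer(seed)),
    class = "train_schedule")
}

#' Forecast every window of a split in batches
#'
#' @param model a fitted forecaster
#' @param w a `gb_windows`
#' @param batch_size windows per forward pass
#' @return list with arrays `pred` and `true` (N x t_f x n_windows)
#' @export
predict_windows <- function(model, w, batch_size = 64L) {
  nw <- n_windows(w)
  if (nw == 0L) stop("no windows to forecast")
  chunks <- split(seq_len(nw), ceiling(seq_len(nw) / batch_size))
  pred <- NULL; true <- NULL
  for (idx in chunks) {
    b <- window_batch(w, idx)
    p <- forecast(model, b$past, t_f = w$t_f)
    if (is.null(pred)) {
      n <- dim(p)[1L]
      pred <- array(0, c(n, w$t_f, nw))
      true <- array(0, c(n, w$t_f, nw))
    }
    pred[, , idx] <- p
    true[, , idx] <- b$future
  }
  list(pred = pred, true = true)
}

#' Train a forecaster on prepared splits
#'
#' Minimizes minibatch MAE with Adam under the schedule's learning-rate
#' plan. Validation MAE is computed once per epoch in evaluation mode (the
#' recurrent decoder feeds its own predictions); the weights with the lowest
#' validation error are restored before each decay and at the end.
#'
#' @param model a `dcrnn_model`, `gwn_model` or `tatt_model`
#' @param splits list with `train` and `val` `gb_windows` (from
#'   [split_windows()])
#' @param schedule a [train_schedule()]
#' @param verbose print per-epoch progress
#' @return list with `model` (best-validation weights), `history` (tibble
#'   of epoch, train_mae, val_mae, lr) and `best_val`
#' @export
train_model <- function(model, splits, schedule, verbose = FALSE) {
  stopifnot(inherits(schedule, "train_schedule"))
  train_w <- splits$train
  n_train <- n_windows(train_w)
  if (n_train == 0L) stop("empty training split")
  params <- gb_collect_params(model)
  opt <- gb_adam_init(params)
  set.seed(schedule$seed)
  lr <- schedule$lr
  decays_left <- schedule$decay_epochs
  best_val <- Inf
  best_weights <- gb_param_values(params)
  since_improve <- 0L
  iter <- 0L
  history <- vector("list", schedule$epochs)
  for (epoch in seq_len(schedule$epochs)) {
    ord <- sample.int(n_train)
    batches <- split(ord, ceiling(seq_along(ord) / schedule$batch_size))
    epoch_loss <- 0
    for (bidx in batches) {
      bat <- window_batch(train_w, bidx)
      gb_zero_grad(params)
      loss <- gb_model_loss(model, bat$past, bat$future,
                            list(iter = iter, training = TRUE))
      if (!is.finite(loss$val[1L]))
        stop(sprintf("divergent loss at epoch %d (non-finite objective)",
                     epoch))
      gb_backward(loss)
      opt <- gb_adam_step(opt, params, lr, clip = schedule$clip)
      epoch_loss <- epoch_loss + loss$val[1L] * length(bidx)
      iter <- iter + 1L
    }
    train_mae <- epoch_loss / n_train
    val_fc <- predict_windows(model, splits$val)
    val_mae <- mae(val_fc$true, val_fc$pred)
    history[[epoch]] <- tibble::tibble(epoch = epoch, train_mae = train_mae,
                                       val_mae = val_mae, lr = lr)
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f  lr %.2g",
                      epoch, train_mae, val_mae, lr))
    if (val_mae < best_val) {
      best_val <- val_mae
      best_weights <- gb_param_values(params)
      since_improve <- 0L
    } else {
      since_improve <- since_improve + 1L
    }
    plateau <- since_improve > schedule$patience
    scheduled <- length(decays_left) > 0L && epoch >= decays_left[1L]
    if (scheduled || plateau) {
      gb_param_restore(params, best_weights)
      lr <- lr * schedule$decay_factor
      if (length(decays_left) > 0L) decays_left <- decays_left[-1L]
      since_improve <- 0L
    }
  }
  gb_param_restore(params, best_weights)
  structure(list(model = model, history = do.call(rbind, history),
                 best_val = best_val),
            class = "gb_fit")
}

#' @export
print.gb_fit <- function(x, ...) {
  cat(sprintf("<gb_fit: %s, %d epochs, best validation MAE %.4f>\n",
              class(x$model)[1], nrow(x$history), x$best_val))
  invisible(x)
}

#' Tidy training history of a [train_model()] result
#' @param x a `train_model` result
#' @param ... unused
#' @export
tidy.gb_fit <- function(x, ...) x$history

#' Evaluate a fitted forecaster on a window split
#'
#' Computes the MAE, per-horizon MAE, pooled R-squared, and mean FC-state
#' similarity (per-window Pearson correlation between the upper triangles
#' of predicted and true N x N correlation matrices).
#'
#' @param model a fitted forecaster
#' @param w a `gb_windows` (typically the test split)
#' @param metrics subset of `c("mae", "horizon", "r2", "fc")`
#' @param batch_size forward-pass batch size
#' @return list with the requested metrics (`horizon` is a vector)
#' @export
evaluate_model <- function(model, w,
                           metrics = c("mae", "horizon", "r2", "fc"),
                           batch_size = 64L) {
  fc <- predict_windows(model, w, batch_size)
  out <- list()
  if ("mae" %in% metrics) out$mae <- mae(fc$true, fc$pred)
  if ("horizon" %in% metrics) out$horizon <- horizon_mae(fc$true, fc$pred)
  if ("r2" %in% metrics) out$r2 <- r_squared(fc$true, fc$pred)
  if ("fc" %in% metrics) {
    sims <- vapply(seq_len(dim(fc$pred)[3L]), function(i) {
      tryCatch(fc_similarity(fc$pred[, , i], fc$true[, , i]),
               error = function(e) NA_real_)
    }, numeric(1))
    out$fc_similarity <- mean(sims, na.rm = TRUE)
  }
  out
}

#' Band-pass, scale, window and split sessions in one call
#'
#' The standard preparation pipeline: optional band-pass filter, session
#' min-max scaling to \[0, 1\] (statistics over the full session, matching
#' the training convention; set `scale_train_only = TRUE` for a strict
#' variant using only the training stretch), windowing, and the
#' chronological 80/10/10 split.
#'
#' @param sessions list of [session_ts()]
#' @param t_p,t_f window lengths
#' @param band NULL or c(low, high) in Hz
#' @param scale_mode `"minmax01"`, `"zscore"` or `"none"`
#' @param scale_train_only compute min-max statistics from the training
#'   stretch only
#' @param fractions split fractions
#' @return list with `splits` (train/val/test `gb_windows`) and
#'   `scaling` (the `scaling_params`, or NULL)
#' @export
prepare_data <- function(sessions, t_p = 60L, t_f = 60L, band = NULL,
                         scale_mode = "minmax01", scale_train_only = FALSE,
                         fractions = c(0.8, 0.1, 0.1)) {
  if (inherits(sessions, "session_ts")) sessions <- list(sessions)
  if (!is.null(band))
    sessions <- lapply(sessions, bandpass_filter, low_hz = band[1L],
                       high_hz = band[2L])
  scaling <- NULL
  if (scale_mode != "none") {
    if (scale_mode == "minmax01" && scale_train_only) {
      # statistics from the stretch covered by training windows only
      sessions <- lapply(sessions, function(s) {
        tt <- ncol(s$values)
        cnt <- tt - t_p - t_f + 1L
        n_train <- cnt - 2L * floor(0.1 * cnt)
        seg <- s$values[, seq_len(n_train + t_p + t_f - 1L), drop = FALSE]
        lo <- min(seg); hi <- max(seg)
        session_ts((s$values - lo) / (hi - lo), s$sampling_interval,
                   s$session_id)
      })
    } else {
      sc <- scale_signals(sessions, scale_mode)
      sessions <- sc$data
      scaling <- sc$params
    }
  }
  w <- make_windows(sessions, t_p, t_f)
  list(splits = split_windows(w, fractions), scaling = scaling,
       windows = w)
}
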