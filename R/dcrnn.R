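# Diffusion-convolution recurrent network: DCGRU cells in an encoder-decoder
# sequence-to-sequence forecaster with scheduled sampling.

#' Scheduled-sampling probability
#'
#' Probability eps_i = tau / (tau + exp(i / tau)) of feeding the decoder the
#' true value (rather than its own previous prediction) at training
#' iteration i. Strictly decreasing in i with limit 0.
#'
#' @param i iteration counter (>= 0)
#' @param tau decay parameter (> 0); default 2000 iterations
#' @return probability in (0, 1\]
#' @export
scheduled_sampling_prob <- function(i, tau = 2000) {
  if (tau <= 0) stop("tau must be positive")
  if (any(i < 0)) stop("iteration counter must be nonnegative")
  tau / (tau + exp(i / tau))
}

# one DCGRU cell: three graph-conv layers acting on [x || h]
gb_dcgru_cell_init <- function(c_in, hidden, spat) {
  list(r = gb_gconv_init(c_in + hidden, hidden, spat),
       u = gb_gconv_init(c_in + hidden, hidden, spat),
       c = gb_gconv_init(c_in + hidden, hidden, spat))
}

# autodiff DCGRU update; x and h_prev are (B*N) x C nodes
gb_dcgru_step <- function(x, h_prev, cell, spat, v_node) {
  xh <- gb_cbind(list(x, h_prev))
  r <- gb_sigmoid(gb_gconv_apply(xh, cell$r, spat, v_node))
  u <- gb_sigmoid(gb_gconv_apply(xh, cell$u, spat, v_node))
  xc <- gb_cbind(list(x, gb_mul(r, h_prev)))
  cc <- gb_tanh(gb_gconv_apply(xc, cell$c, spat, v_node))
  gb_add(gb_mul(u, h_prev), gb_mul(gb_sub(1, u), cc))
}

#' Construct a DCRNN forecaster
#'
#' Encoder and decoder each stack `layers` DCGRU cells; spatial mixing
#' inside every gate follows the supplied [spatial_spec()]. The output head
#' is an affine map from the final decoder layer's hidden state to one
#' feature per node per step.
#'
#' @param spatial a [spatial_spec()]
#' @param t_p,t_f input and forecast horizon lengths
#' @param hidden hidden state size (default 64)
#' @param layers DCGRU layers in encoder and decoder (default 2)
#' @param tau scheduled-sampling decay parameter
#' @param seed integer seed for weight initialization
#' @return a `dcrnn_model`
#' @export
dcrnn <- function(spatial, t_p, t_f, hidden = 64L, layers = 2L,
                  tau = 2000, seed = 1L) {
  set.seed(seed)
  v_node <- if (spatial$mode %in% c("adaptive", "hybrid"))
    gb_param(matrix(0, spatial$n_nodes, spatial$n_nodes)) else NULL
  make_stack <- function() lapply(seq_len(layers), function(l) {
    gb_dcgru_cell_init(if (l == 1L) 1L else hidden, hidden, spatial)
  })
  model <- structure(list(
    spatial = spatial, t_p = as.integer(t_p), t_f = as.integer(t_f),
    hidden = as.integer(hidden), layers = as.integer(layers), tau = tau,
    v = v_node,
    encoder = make_stack(), decoder = make_stack(),
    w_out = gb_param(gb_glorot(hidden, 1L)),
    b_out = gb_param(matrix(0, 1L, 1L))),
    class = "dcrnn_model")
  model
}

#' @export
print.dcrnn_model <- function(x, ...) {
  np <- sum(vapply(gb_collect_params(x), function(p) length(p$val),
                   numeric(1)))
  cat(sprintf(
    "<dcrnn_model: %d regions, %d layers, hidden %d, K = %d (%s), %d parameters>\n",
    x$spatial$n_nodes, x$layers, x$hidden, x$spatial$k, x$spatial$mode, np))
  invisible(x)
}

# full seq2seq forward; returns list over t_f of (B*N) x 1 prediction nodes.
# `teacher` (list of (B*N) x 1 matrices) and `eps` trigger scheduled
# sampling; sampling draws one Bernoulli per decoder step per sample.
gb_dcrnn_forward <- function(model, past_steps, teacher = NULL, eps = 0,
                             batch = 1L) {
  spat <- model$spatial
  bn <- nrow(past_steps[[1L]])
  n <- spat$n_nodes
  h <- lapply(seq_len(model$layers),
              function(l) gb_const(matrix(0, bn, model$hidden)))
  for (t in seq_along(past_steps)) {
    inp <- gb_const(past_steps[[t]])
    for (l in seq_len(model$layers)) {
      h[[l]] <- gb_dcgru_step(inp, h[[l]], model$encoder[[l]], spat, model$v)
      inp <- h[[l]]
    }
  }
  preds <- vector("list", model$t_f)
  dec_in <- gb_const(matrix(0, bn, 1L))   # <GO> symbol
  for (s in seq_len(model$t_f)) {
    inp <- dec_in
    for (l in seq_len(model$layers)) {
      h[[l]] <- gb_dcgru_step(inp, h[[l]], model$decoder[[l]], spat, model$v)
      inp <- h[[l]]
    }
    preds[[s]] <- gb_add(gb_matmul(h[[model$layers]], model$w_out),
                         model$b_out)
    if (s < model$t_f) {
      if (!is.null(teacher) && eps > 0) {
        use_true <- stats::rbinom(batch, 1L, eps)
        mask <- matrix(rep(use_true, each = n), bn, 1L)
        dec_in <- gb_add(gb_const(mask * teacher[[s]]),
                         gb_mul(gb_const(1 - mask), preds[[s]]))
      } else {
        dec_in <- preds[[s]]
      }
    }
  }
  preds
}

#' One DCGRU cell update on plain matrices
#'
#' Convenience wrapper exposing the gated update
#' `h_t = u (.) h_prev + (1 - u) (.) c` for inspection and testing.
#'
#' @param model a [dcrnn()] model
#' @param x N x 1 (or (B*N) x 1) input feature matrix
#' @param h_prev matching hidden-state matrix (columns = hidden channels)
#' @param layer which layer's cell to use
#' @param stack `"encoder"` or `"decoder"`
#' @return the updated hidden state as a plain matrix
#' @export
dcgru_step <- function(model, x, h_prev, layer = 1L, stack = "encoder") {
  cell <- model[[stack]][[layer]]
  node <- gb_dcgru_step(gb_const(as.matrix(x)), gb_const(as.matrix(h_prev)),
                        cell, model$spatial, model$v)
  node$val
}

#' @describeIn dcrnn Forecast with a (trained) DCRNN; evaluation mode, the
#'   decoder always consumes its own previous prediction.
#' @param model a `dcrnn_model`
#' @param past N x t_p matrix or N x t_p x B array
#' @param ... unused
#' @export
forecast.dcrnn_model <- function(model, past, ...) {
  arr <- gb_as_batch_array(past)
  b <- dim(arr)[3L]
  steps <- gb_stack_batch(arr)
  preds <- gb_dcrnn_forward(model, steps, teacher = NULL, eps = 0, batch = b)
  out <- do.call(cbind, lapply(preds, function(p) p$val))
  res <- gb_unstack_batch(out, model$spatial$n_nodes)
  if (length(dim(past)) == 2L) res[, , 1L] else res
}

# training loss for one minibatch (used by train_model)
gb_model_loss <- function(model, past_arr, future_arr, ctx) {
  UseMethod("gb_model_loss")
}

#' @export
gb_model_loss.dcrnn_model <- function(model, past_arr, future_arr, ctx) {
  b <- dim(past_arr)[3L]
  steps <- gb_stack_batch(past_arr)
  teacher <- gb_stack_batch(future_arr)
  eps <- scheduled_sampling_prob(ctx$iter, model$tau)
  preds <- gb_dcrnn_forward(model, steps, teacher = teacher, eps = eps,
                            batch = b)
  target <- do.call(cbind, teacher)
  gb_loss_mae(gb_cbind(preds), target)
}
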