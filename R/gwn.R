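# Graph WaveNet: gated dilated causal temporal convolutions interleaved with
# graph convolutions, residual and skip connections, and a dense two-layer
# output head emitting the full horizon in one shot.

#' Dilated causal convolution of a channel-by-time sequence
#'
#' `y[, t] = sum_{r=0}^{R-1} Theta_r x[, t - d*r]`, with left zero padding
#' so the output has the input's length and position t depends only on
#' inputs at t, t-d, ..., t-d(R-1).
#'
#' @param xseq channels x T input matrix
#' @param theta kernel array (R, C_out, C_in); a numeric vector is treated
#'   as a width-R scalar kernel on a single channel
#' @param d dilation factor (>= 1)
#' @return C_out x T matrix
#' @export
dilated_causal_conv <- function(xseq, theta, d = 1L) {
  if (d < 1L) stop("dilation factor must be >= 1")
  xseq <- as.matrix(xseq)
  if (is.null(dim(theta)) || length(dim(theta)) == 1L)
    theta <- array(theta, c(length(theta), 1L, 1L))
  if (length(dim(theta)) == 2L) theta <- array(theta, c(dim(theta), 1L))
  r_w <- dim(theta)[1L]
  if (r_w < 1L) stop("kernel width must be >= 1")
  c_out <- dim(theta)[2L]; c_in <- dim(theta)[3L]
  if (nrow(xseq) != c_in) stop("input channel mismatch")
  tt <- ncol(xseq)
  out <- matrix(0, c_out, tt)
  for (r in 0:(r_w - 1L)) {
    th <- matrix(theta[r + 1L, , ], c_out, c_in)
    valid <- (1L + d * r):tt
    if (length(valid) < 1L || valid[1L] > tt) next
    out[, valid] <- out[, valid, drop = FALSE] +
      th %*% xseq[, valid - d * r, drop = FALSE]
  }
  out
}

#' Gated temporal convolution
#'
#' `h = tanh(DCC(Theta_1) x + b_1) (.) logistic(DCC(Theta_2) x + b_2)`:
#' the tanh branch filters, the logistic branch gates.
#'
#' @param xseq channels x T input matrix
#' @param params list with `theta1`, `b1`, `theta2`, `b2` (biases per output
#'   channel)
#' @param d dilation factor
#' @return C_out x T matrix with entries in (-1, 1)
#' @export
gated_tcn <- function(xseq, params, d = 1L) {
  filt <- tanh(dilated_causal_conv(xseq, params$theta1, d) + params$b1)
  gate <- 1 / (1 + exp(-(dilated_causal_conv(xseq, params$theta2, d) +
                           params$b2)))
  filt * gate
}

# autodiff dilated conv on a list of per-time (B*N) x C state nodes
gb_dcc_apply <- function(states, wlist, bias, d) {
  tt <- length(states)
  lapply(seq_len(tt), function(t) {
    terms <- list()
    for (r in seq_along(wlist)) {
      src <- t - d * (r - 1L)
      if (src >= 1L)
        terms[[length(terms) + 1L]] <- gb_matmul(states[[src]], wlist[[r]])
    }
    pre <- if (length(terms) == 1L) terms[[1L]] else gb_sum_list(terms)
    gb_add(pre, bias)
  })
}

#' Construct a graph WaveNet forecaster
#'
#' `blocks` blocks of `layers_per_block` gated temporal layers; the dilation
#' doubles within each block (1, 2, ...) and the schedule repeats across
#' blocks. Each layer applies the gated TCN, then a graph convolution at
#' every time index, adds a residual connection, and feeds a skip branch;
#' the summed skips pass through two dense layers that emit all t_f steps at
#' once.
#'
#' @param spatial a [spatial_spec()]
#' @param t_p,t_f input and forecast horizon lengths
#' @param channels residual/skip channel width (default 32)
#' @param blocks number of blocks (default 12)
#' @param layers_per_block gated layers per block (default 2)
#' @param kernel causal kernel width R (default 2)
#' @param seed integer seed for weight initialization
#' @return a `gwn_model`
#' @export
gwn <- function(spatial, t_p, t_f, channels = 32L, blocks = 12L,
                layers_per_block = 2L, kernel = 2L, seed = 1L) {
  if (kernel < 1L) stop("kernel width must be >= 1")
  set.seed(seed)
  v_node <- if (spatial$mode %in% c("adaptive", "hybrid"))
    gb_param(matrix(0, spatial$n_nodes, spatial$n_nodes)) else NULL
  dilations <- rep(2^(seq_len(layers_per_block) - 1L), times = blocks)
  # kernel taps of one conv share an effective fan-in of channels * kernel
  tap_init <- function() {
    lim <- sqrt(6 / (channels * kernel + channels))
    lapply(seq_len(kernel), function(r)
      gb_param(matrix(stats::runif(channels^2, -lim, lim),
                      channels, channels)))
  }
  layers <- lapply(dilations, function(d) {
    list(
      filt_w = tap_init(),
      filt_b = gb_param(matrix(0, 1L, channels)),
      gate_w = tap_init(),
      gate_b = gb_param(matrix(0, 1L, channels)),
      gconv = gb_gconv_init(channels, channels, spatial),
      d = d)
  })
  structure(list(
    spatial = spatial, t_p = as.integer(t_p), t_f = as.integer(t_f),
    channels = as.integer(channels), blocks = as.integer(blocks),
    layers_per_block = as.integer(layers_per_block),
    kernel = as.integer(kernel), dilations = dilations, v = v_node,
    w_in = gb_param(gb_glorot(1L, channels)),
    b_in = gb_param(matrix(0, 1L, channels)),
    layers = layers,
    w_head1 = gb_param(gb_glorot(channels * t_p, channels)),
    b_head1 = gb_param(matrix(0, 1L, channels)),
    w_head2 = gb_param(gb_glorot(channels, t_f)),
    b_head2 = gb_param(matrix(0, 1L, t_f))),
    class = "gwn_model")
}

#' @export
print.gwn_model <- function(x, ...) {
  np <- sum(vapply(gb_collect_params(x), function(p) length(p$val),
                   numeric(1)))
  cat(sprintf(
    "<gwn_model: %d regions, %d gated layers (RF %d), %d channels, K = %d (%s), %d parameters>\n",
    x$spatial$n_nodes, length(x$layers), gwn_receptive_field(x),
    x$channels, x$spatial$k, x$spatial$mode, np))
  invisible(x)
}

#' Receptive field of a GWN configuration
#'
#' Closed form `1 + (R - 1) * sum(dilations)`: the earliest past step that
#' can influence the temporal stack's output.
#'
#' @param model a `gwn_model`
#' @return integer receptive field in time steps
#' @export
gwn_receptive_field <- function(model) {
  1L + (model$kernel - 1L) * sum(model$dilations)
}

# forward pass up to the dense head; returns the (B*N) x t_f output node
gb_gwn_forward <- function(model, past_steps) {
  spat <- model$spatial
  states <- lapply(past_steps, function(x)
    gb_add(gb_matmul(gb_const(x), model$w_in), model$b_in))
  skip <- NULL
  for (layer in model$layers) {
    filt <- gb_dcc_apply(states, layer$filt_w, layer$filt_b, layer$d)
    gate <- gb_dcc_apply(states, layer$gate_w, layer$gate_b, layer$d)
    gated <- lapply(seq_along(states), function(t)
      gb_mul(gb_tanh(filt[[t]]), gb_sigmoid(gate[[t]])))
    gc_out <- lapply(gated, function(x)
      gb_relu(gb_gconv_apply(x, layer$gconv, spat, model$v)))
    skip <- if (is.null(skip)) gc_out
            else lapply(seq_along(states), function(t)
              gb_add(skip[[t]], gc_out[[t]]))
    states <- lapply(seq_along(states), function(t)
      gb_add(states[[t]], gc_out[[t]]))
  }
  flat <- gb_cbind(lapply(skip, gb_relu))          # (B*N) x (C * t_p)
  hid <- gb_relu(gb_add(gb_matmul(flat, model$w_head1), model$b_head1))
  gb_add(gb_matmul(hid, model$w_head2), model$b_head2)
}

#' @describeIn gwn Forecast with a (trained) GWN; emits all horizon steps in
#'   one shot.
#' @param model a `gwn_model`
#' @param past N x t_p matrix or N x t_p x B array
#' @param ... unused
#' @export
forecast.gwn_model <- function(model, past, ...) {
  arr <- gb_as_batch_array(past)
  steps <- gb_stack_batch(arr)
  out <- gb_gwn_forward(model, steps)
  res <- gb_unstack_batch(out$val, model$spatial$n_nodes)
  if (length(dim(past)) == 2L) res[, , 1L] else res
}

#' @export
gb_model_loss.gwn_model <- function(model, past_arr, future_arr, ctx) {
  steps <- gb_stack_batch(past_arr)
  out <- gb_gwn_forward(model, steps)
  target <- do.call(cbind, gb_stack_batch(future_arr))
  gb_loss_mae(out, target)
}
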