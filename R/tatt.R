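# Temporal-attention forecaster: stacked causal attention layers with
# residual connections and batch normalization. The model mixes information
# across time only, never across regions, so region permutation commutes
# with the forecast.

#' Causal temporal relevance scores for one node sequence
#'
#' Projects each time step with `g(x) = ReLU(W x + b)`, scores pairs by the
#' scaled inner product `g(q) . g(k) / D`, and normalizes each row with a
#' causal softmax over time steps `t_j <= t_i` (the first step has no strict
#' predecessor, so the mask is relaxed to include the current step
#' everywhere).
#'
#' @param node_seq T x M matrix: one node's feature sequence over time
#' @param params list with `W` (D x M projection) and `b` (length-D offset)
#' @return T x T matrix of normalized scores; row i is a probability
#'   distribution supported on columns j <= i
#' @export
temporal_relevance <- function(node_seq, params) {
  x <- as.matrix(node_seq)
  d <- nrow(as.matrix(params$W))
  g <- pmax(x %*% t(params$W) + matrix(params$b, nrow(x), d, byrow = TRUE), 0)
  raw <- tcrossprod(g) / d
  tt <- nrow(x)
  out <- matrix(0, tt, tt)
  for (i in seq_len(tt)) {
    adm <- seq_len(i)
    e <- exp(raw[i, adm] - max(raw[i, adm]))
    out[i, adm] <- e / sum(e)
  }
  out
}

#' Normalized relevance weights from raw attention scores
#'
#' The softmax normalization used over the admissible (causal) time steps:
#' `exp(s_j) / sum_j exp(s_j)`. Scores of (1, 0) give weights
#' (e/(e+1), 1/(e+1)) = (0.7311, 0.2689).
#'
#' @param scores numeric vector of raw (already scaled) scores
#' @return probability vector of the same length
#' @export
relevance_weights <- function(scores) {
  e <- exp(scores - max(scores))
  e / sum(e)
}

# one attention layer's parameters
gb_tatt_layer_init <- function(m, heads) {
  d <- m %/% heads
  list(
    heads = lapply(seq_len(heads), function(h) list(
      w = gb_param(gb_glorot(m, d)),
      b = gb_param(matrix(0, 1L, d)))),
    w_o = gb_param(gb_glorot(m, m)),
    b_o = gb_param(matrix(0, 1L, m)),
    gamma = gb_param(matrix(1, 1L, m)),
    beta = gb_param(matrix(0, 1L, m)),
    stats = new.env(parent = emptyenv()))
}

# autodiff attention layer over a list of per-time (B*N) x M states
gb_tatt_layer <- function(states, layer, heads, training) {
  tt <- length(states)
  m <- ncol(states[[1L]]$val)
  d <- m %/% heads
  ctx <- vector("list", tt)            # per time: list of per-head contexts
  for (h in seq_len(heads)) {
    hp <- layer$heads[[h]]
    g <- lapply(states, function(x)
      gb_relu(gb_add(gb_matmul(x, hp$w), hp$b)))
    for (i in seq_len(tt)) {
      raw <- lapply(seq_len(i), function(j)
        gb_scale(gb_rowdot(g[[i]], g[[j]]), 1 / d))
      ex <- lapply(raw, gb_exp)
      z <- if (length(ex) == 1L) ex[[1L]] else gb_sum_list(ex)
      weighted <- lapply(seq_len(i), function(j)
        gb_mul(gb_div(ex[[j]], z), g[[j]]))
      head_ctx <- if (length(weighted) == 1L) weighted[[1L]]
                  else gb_sum_list(weighted)
      ctx[[i]] <- c(ctx[[i]], list(head_ctx))
    }
  }
  out <- lapply(seq_len(tt), function(i) {
    cat_heads <- if (heads == 1L) ctx[[i]][[1L]] else gb_cbind(ctx[[i]])
    att <- gb_relu(gb_add(gb_matmul(cat_heads, layer$w_o), layer$b_o))
    gb_add(states[[i]], att)           # residual connection
  })
  # batch normalization over all rows of all time steps jointly
  big <- gb_rbind(out)
  big <- gb_batchnorm(big, layer$gamma, layer$beta, layer$stats, training)
  bn <- nrow(states[[1L]]$val)
  lapply(seq_len(tt), function(i) gb_rows(big, (i - 1L) * bn + seq_len(bn)))
}

#' Construct a temporal-attention forecaster
#'
#' The single-feature input is projected to `m` features, passed through
#' `layers` causal attention layers (each with `heads` heads on disjoint
#' feature slices, a residual connection and batch normalization), collapsed
#' back to one feature, and mapped from the t_p input positions to the t_f
#' output positions by a learned affine map over the time axis. All
#' attention parameters are shared across nodes and time steps.
#'
#' @param n_nodes number of regions
#' @param t_p,t_f input and forecast horizon lengths
#' @param m feature width (default 32); must be divisible by `heads`
#' @param heads attention heads (default 4)
#' @param layers stacked attention layers (default 4)
#' @param seed integer seed for weight initialization
#' @return a `tatt_model`
#' @export
tatt <- function(n_nodes, t_p, t_f, m = 32L, heads = 4L, layers = 4L,
                 seed = 1L) {
  if (m %% heads != 0L) stop("feature width m must be divisible by heads")
  set.seed(seed)
  structure(list(
    n_nodes = as.integer(n_nodes), t_p = as.integer(t_p),
    t_f = as.integer(t_f), m = as.integer(m), heads = as.integer(heads),
    n_layers = as.integer(layers),
    w_in = gb_param(gb_glorot(1L, m)),
    b_in = gb_param(matrix(0, 1L, m)),
    layers = lapply(seq_len(layers), function(l) gb_tatt_layer_init(m, heads)),
    w_feat = gb_param(gb_glorot(m, 1L)),
    b_feat = gb_param(matrix(0, 1L, 1L)),
    w_time = gb_param(gb_glorot(t_p, t_f)),
    b_time = gb_param(matrix(0, 1L, t_f))),
    class = "tatt_model")
}

#' @export
print.tatt_model <- function(x, ...) {
  np <- sum(vapply(gb_collect_params(x), function(p) length(p$val),
                   numeric(1)))
  cat(sprintf(
    "<tatt_model: %d regions, %d layers x %d heads, width %d, %d parameters>\n",
    x$n_nodes, x$n_layers, x$heads, x$m, np))
  invisible(x)
}

# forward to the (B*N) x t_f output node
gb_tatt_forward <- function(model, past_steps, training = FALSE) {
  states <- lapply(past_steps, function(x)
    gb_add(gb_matmul(gb_const(x), model$w_in), model$b_in))
  for (layer in model$layers)
    states <- gb_tatt_layer(states, layer, model$heads, training)
  feat <- lapply(states, function(x)
    gb_add(gb_matmul(x, model$w_feat), model$b_feat))
  seq_mat <- gb_cbind(feat)                       # (B*N) x t_p
  gb_add(gb_matmul(seq_mat, model$w_time), model$b_time)
}

#' Apply one attention layer to a feature array
#'
#' Numeric convenience wrapper around a fitted model's layer for inspection
#' and testing: shape-preserving N x T x M in and out.
#'
#' @param model a [tatt()] model
#' @param h N x T x M feature array
#' @param layer layer index
#' @param training use batch statistics (`TRUE`) or running averages in the
#'   batch-normalization step
#' @return N x T x M array
#' @export
attention_layer <- function(model, h, layer = 1L, training = TRUE) {
  h <- as.array(h)
  d <- dim(h)
  states <- lapply(seq_len(d[2L]), function(t)
    gb_const(matrix(h[, t, ], d[1L], d[3L])))
  out <- gb_tatt_layer(states, model$layers[[layer]], model$heads, training)
  res <- array(0, d)
  for (t in seq_len(d[2L])) res[, t, ] <- out[[t]]$val
  res
}

#' @describeIn tatt Forecast with a (trained) temporal-attention model.
#' @param model a `tatt_model`
#' @param past N x t_p matrix or N x t_p x B array
#' @param ... unused
#' @export
forecast.tatt_model <- function(model, past, ...) {
  arr <- gb_as_batch_array(past)
  steps <- gb_stack_batch(arr)
  out <- gb_tatt_forward(model, steps, training = FALSE)
  res <- gb_unstack_batch(out$val, model$n_nodes)
  if (length(dim(past)) == 2L) res[, , 1L] else res
}

#' @export
gb_model_loss.tatt_model <- function(model, past_arr, future_arr, ctx) {
  steps <- gb_stack_batch(past_arr)
  out <- gb_tatt_forward(model, steps, training = TRUE)
  target <- do.call(cbind, gb_stack_batch(future_arr))
  gb_loss_mae(out, target)
}
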