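# Shared infrastructure for the neural forecasters: spatial-coupling specs,
# autodiff graph-convolution layers, weight initialization, parameter
# collection, and the Adam optimizer.

#' Spatial coupling specification for a forecaster
#'
#' Decides how (and whether) a model mixes information across regions:
#' `"operator"` uses a fixed transition operator (from structural or
#' connectome-embedding adjacency), `"adaptive"` learns a normalized
#' adaptive adjacency tanh(V)/N from scratch, `"hybrid"` sums both operator
#' families, and `"none"` disables spatial mixing (equivalent to walk order
#' K = 0).
#'
#' @param mode one of `"operator"`, `"adaptive"`, `"hybrid"`, `"none"`
#' @param operator a [transition_matrix()] result or bare N x N matrix
#'   (required for `"operator"` and `"hybrid"`)
#' @param k maximum walk order K of the power-series filters
#' @param n_nodes number of regions (required for `"adaptive"` when no
#'   operator is given)
#' @return a `spatial_spec`
#' @export
spatial_spec <- function(mode = c("operator", "adaptive", "hybrid", "none"),
                         operator = NULL, k = 1L, n_nodes = NULL) {
  mode <- match.arg(mode)
  tm <- NULL
  if (mode %in% c("operator", "hybrid")) {
    if (is.null(operator)) stop("mode '", mode, "' requires an operator")
    tm <- if (inherits(operator, "transition_operator")) operator$T
          else as.matrix(operator)
    n_nodes <- nrow(tm)
  }
  if (mode == "none") k <- 0L
  if (is.null(n_nodes)) stop("n_nodes required when no operator is given")
  structure(list(mode = mode, operator = tm, k = as.integer(k),
                 n_nodes = as.integer(n_nodes)),
            class = "spatial_spec")
}

# number of power-series branches a spec contributes
gb_spatial_branches <- function(spat) {
  switch(spat$mode, none = 1L, operator = 1L, adaptive = 1L, hybrid = 2L)
}

# Glorot-uniform init; draws from the current R RNG stream
gb_glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

# Initialize one graph-convolution layer: per branch, one (c_in x c_out)
# coefficient matrix per walk order k = 0..K, plus a shared bias. The init
# scale treats the full power series as one layer whose effective fan-in is
# c_in * (K+1) * branches.
gb_gconv_init <- function(c_in, c_out, spat) {
  branches <- gb_spatial_branches(spat)
  k <- spat$k
  lim <- sqrt(6 / (c_in * (k + 1L) * branches + c_out))
  w <- lapply(seq_len(branches), function(b)
    lapply(0:k, function(kk)
      gb_param(matrix(stats::runif(c_in * c_out, -lim, lim), c_in, c_out))))
  list(w = w, b = gb_param(matrix(0, 1L, c_out)))
}

# Apply a graph-convolution layer on a batch-stacked state (B*N) x c_in.
# `v_node` is the model's shared adaptive parameter node (or NULL).
gb_gconv_apply <- function(x, layer, spat, v_node = NULL, bias = TRUE) {
  n <- spat$n_nodes
  terms <- list()
  add_branch <- function(opm, wlist) {
    tkx <- x
    for (kk in 0:spat$k) {
      if (kk > 0L) tkx <- gb_graphmul(opm, tkx, n)
      terms[[length(terms) + 1L]] <<- gb_matmul(tkx, wlist[[kk + 1L]])
    }
  }
  if (spat$mode %in% c("operator", "hybrid"))
    add_branch(spat$operator, layer$w[[1L]])
  if (spat$mode %in% c("adaptive", "hybrid")) {
    a_adap <- gb_scale(gb_tanh(v_node), 1 / n)
    add_branch(a_adap, layer$w[[length(layer$w)]])
  }
  if (spat$mode == "none")
    terms[[1L]] <- gb_matmul(x, layer$w[[1L]][[1L]])
  pre <- if (length(terms) == 1L) terms[[1L]] else gb_sum_list(terms)
  if (bias) gb_add(pre, layer$b) else pre
}

# Collect every parameter node buried in a nested model structure.
gb_collect_params <- function(x) {
  out <- list()
  walk <- function(v) {
    if (inherits(v, "gb_node")) {
      if (v$is_param) out[[length(out) + 1L]] <<- v
    } else if (is.list(v)) {
      for (el in v) walk(el)
    }
  }
  walk(x)
  out
}

# deep-copy parameter values (for best-checkpoint restore)
gb_param_values <- function(params) lapply(params, function(p) p$val)
gb_param_restore <- function(params, values) {
  for (i in seq_along(params)) params[[i]]$val <- values[[i]]
  invisible(NULL)
}

# -- Adam --------------------------------------------------------------------

gb_adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p$val))),
       v = lapply(params, function(p) array(0, dim(p$val))),
       t = 0L)
}

# One Adam update; `clip` is an optional global gradient-norm bound.
gb_adam_step <- function(state, params, lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, clip = NULL) {
  grads <- lapply(params, function(p) {
    if (is.null(p$grad)) array(0, dim(p$val)) else p$grad
  })
  if (!is.null(clip)) {
    gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
    if (is.finite(gnorm) && gnorm > clip)
      grads <- lapply(grads, function(g) g * (clip / gnorm))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    g <- grads[[i]]
    state$m[[i]] <- beta1 * state$m[[i]] + (1 - beta1) * g
    state$v[[i]] <- beta2 * state$v[[i]] + (1 - beta2) * g^2
    mhat <- state$m[[i]] / bc1
    vhat <- state$v[[i]] / bc2
    params[[i]]$val <- params[[i]]$val - lr * mhat / (sqrt(vhat) + eps)
  }
  state
}

# -- batch layout helpers ----------------------------------------------------

# N x T x B array -> list over time of (B*N) x 1 matrices (batch-major rows)
gb_stack_batch <- function(arr) {
  d <- dim(arr)
  lapply(seq_len(d[2L]), function(t) {
    matrix(aperm(arr[, t, , drop = FALSE], c(1L, 3L, 2L)), d[1L] * d[3L], 1L)
  })
}

# (B*N) x T matrix -> N x T x B array
gb_unstack_batch <- function(m, n_nodes) {
  b <- nrow(m) %/% n_nodes
  aperm(array(m, c(n_nodes, b, ncol(m))), c(1L, 3L, 2L))
}

# coerce an N x T matrix or N x T x B array to the 3-d form
gb_as_batch_array <- function(past) {
  if (length(dim(past)) == 2L) array(past, c(dim(past), 1L))
  else as.array(past)
}

#' Forecast future activity from a past window
#'
#' Dispatches on the fitted model class (`dcrnn_model`, `gwn_model`,
#' `tatt_model`, `var_model`, or the analytic `linear_model`).
#'
#' @param model a fitted forecaster
#' @param past N x t_p matrix, or N x t_p x B array for a batch
#' @param ... passed to methods
#' @return N x t_f matrix (or N x t_f x B array for batched input)
#' @export
forecast <- function(model, past, ...) UseMethod("forecast")

#' @export
forecast.var_model <- function(model, past, ...) {
  if (length(dim(past)) == 3L) {
    b <- dim(past)[3L]
    t_f <- list(...)$t_f %||% dim(past)[2L]
    out <- array(0, c(model$n, t_f, b))
    for (i in seq_len(b)) out[, , i] <- forecast_var(model, past[, , i], t_f)
    return(out)
  }
  forecast_var(model, past, list(...)$t_f %||% ncol(past))
}

#' Analytic linear forecaster x_{t+1} = C x_t
#'
#' Iterates a fixed coefficient matrix from the last observed state; used as
#' a closed-form reference model for the influence measure.
#'
#' @param coef N x N coefficient matrix
#' @param t_f forecast horizon
#' @return a `linear_model`
#' @export
linear_model <- function(coef, t_f) {
  structure(list(coef = as.matrix(coef), t_f = as.integer(t_f),
                 n_nodes = nrow(coef)),
            class = "linear_model")
}

#' @export
forecast.linear_model <- function(model, past, ...) {
  run1 <- function(m) {
    out <- matrix(0, model$n_nodes, model$t_f)
    x <- m[, ncol(m)]
    for (s in seq_len(model$t_f)) {
      x <- model$coef %*% x
      out[, s] <- x
    }
    out
  }
  if (length(dim(past)) == 3L) {
    b <- dim(past)[3L]
    out <- array(0, c(model$n_nodes, model$t_f, b))
    for (i in seq_len(b)) out[, , i] <- run1(past[, , i])
    return(out)
  }
  run1(past)
}
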