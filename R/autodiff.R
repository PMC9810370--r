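# Reverse-mode automatic differentiation on dense matrices.
#
# Every differentiable quantity is a node: an environment holding the forward
# value (`val`, always a base matrix), its parent nodes, and a vector-Jacobian
# product closure used during the backward sweep.  Nodes are created in
# forward order and carry a monotone id, so a reverse sweep in decreasing id
# order is a valid topological order without an explicit tape object.
#
# The engine is deliberately small: it supports exactly the operations the
# forecasting architectures need (matrix products, per-batch graph operator
# application, element-wise nonlinearities with limited broadcasting, column
# concatenation/slicing, batch normalization, and an L1 loss).

.gb_counter <- new.env(parent = emptyenv())
.gb_counter$id <- 0L

gb_next_id <- function() {
  .gb_counter$id <- .gb_counter$id + 1L
  .gb_counter$id
}

#' @keywords internal
gb_node <- function(val, parents = list(), vjp = NULL) {
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$parents <- parents
  e$vjp <- vjp
  e$pid <- gb_next_id()
  e$is_param <- FALSE
  e$needs <- length(parents) > 0L &&
    any(vapply(parents, function(p) p$needs, logical(1)))
  class(e) <- "gb_node"
  e
}

#' Create a trainable parameter node
#' @param val numeric matrix holding the initial value
#' @return a parameter node whose gradient is populated by `gb_backward()`
#' @keywords internal
gb_param <- function(val) {
  e <- gb_node(as.matrix(val))
  e$is_param <- TRUE
  e$needs <- TRUE
  e$grad <- NULL
  e
}

#' @keywords internal
gb_const <- function(val) gb_node(as.matrix(val))

gb_is_node <- function(x) inherits(x, "gb_node")

gb_wrap <- function(x) if (gb_is_node(x)) x else gb_const(x)

gb_value <- function(x) if (gb_is_node(x)) x$val else x

# -- broadcasting helpers ----------------------------------------------------

# Reduce a full-shape gradient `g` back to the shape of operand `v`.
gb_unbroadcast <- function(g, v) {
  if (nrow(v) == nrow(g) && ncol(v) == ncol(g)) return(g)
  if (nrow(v) == 1L && ncol(v) == 1L) return(matrix(sum(g), 1L, 1L))
  if (nrow(v) == 1L) return(matrix(colSums(g), 1L))
  if (ncol(v) == 1L) return(matrix(rowSums(g), ncol = 1L))
  stop("incompatible broadcast shapes", call. = FALSE)
}

# Expand `v` to shape (n, m) under the same broadcasting rules.
gb_bcast <- function(v, n, m) {
  if (nrow(v) == n && ncol(v) == m) return(v)
  if (nrow(v) == 1L && ncol(v) == 1L) return(matrix(v[1L], n, m))
  if (nrow(v) == 1L) return(matrix(v, n, m, byrow = TRUE))
  if (ncol(v) == 1L) return(matrix(v, n, m))
  stop("incompatible broadcast shapes", call. = FALSE)
}

# -- elementwise arithmetic --------------------------------------------------

gb_add <- function(a, b) {
  a <- gb_wrap(a); b <- gb_wrap(b)
  n <- max(nrow(a$val), nrow(b$val)); m <- max(ncol(a$val), ncol(b$val))
  val <- gb_bcast(a$val, n, m) + gb_bcast(b$val, n, m)
  gb_node(val, list(a, b), function(g) {
    list(gb_unbroadcast(g, a$val), gb_unbroadcast(g, b$val))
  })
}

gb_sub <- function(a, b) {
  a <- gb_wrap(a); b <- gb_wrap(b)
  n <- max(nrow(a$val), nrow(b$val)); m <- max(ncol(a$val), ncol(b$val))
  val <- gb_bcast(a$val, n, m) - gb_bcast(b$val, n, m)
  gb_node(val, list(a, b), function(g) {
    list(gb_unbroadcast(g, a$val), -gb_unbroadcast(g, b$val))
  })
}

gb_mul <- function(a, b) {
  a <- gb_wrap(a); b <- gb_wrap(b)
  n <- max(nrow(a$val), nrow(b$val)); m <- max(ncol(a$val), ncol(b$val))
  av <- gb_bcast(a$val, n, m); bv <- gb_bcast(b$val, n, m)
  gb_node(av * bv, list(a, b), function(g) {
    list(gb_unbroadcast(g * bv, a$val), gb_unbroadcast(g * av, b$val))
  })
}

gb_div <- function(a, b) {
  a <- gb_wrap(a); b <- gb_wrap(b)
  n <- max(nrow(a$val), nrow(b$val)); m <- max(ncol(a$val), ncol(b$val))
  av <- gb_bcast(a$val, n, m); bv <- gb_bcast(b$val, n, m)
  gb_node(av / bv, list(a, b), function(g) {
    list(gb_unbroadcast(g / bv, a$val), gb_unbroadcast(-g * av / bv^2, b$val))
  })
}

gb_scale <- function(a, s) {
  a <- gb_wrap(a)
  gb_node(a$val * s, list(a), function(g) list(g * s))
}

# -- matrix products ---------------------------------------------------------

gb_matmul <- function(a, b) {
  a <- gb_wrap(a); b <- gb_wrap(b)
  gb_node(a$val %*% b$val, list(a, b), function(g) {
    list(g %*% t(b$val), crossprod(a$val, g))
  })
}

# Apply an N x N graph operator to a batch-stacked state matrix.
# `x` has B*N rows (batch-major blocks of N rows) and C channel columns;
# the operator multiplies each batch block from the left.  `op` may be a
# constant matrix or a node (adaptive adjacency), in which case its gradient
# sums the per-batch outer products.
gb_graphmul <- function(op, x, n_nodes) {
  op <- gb_wrap(op); x <- gb_wrap(x)
  bn <- nrow(x$val); cc <- ncol(x$val)
  stopifnot(bn %% n_nodes == 0L)
  bm <- bn %/% n_nodes * cc
  xf <- matrix(x$val, n_nodes, bm)   # N x (B*C), reshape only
  val <- matrix(op$val %*% xf, bn, cc)
  gb_node(val, list(op, x), function(g) {
    gf <- matrix(g, n_nodes, bm)
    g_op <- if (op$needs) tcrossprod(gf, xf) else NULL
    list(g_op, matrix(crossprod(op$val, gf), bn, cc))
  })
}

# -- nonlinearities ----------------------------------------------------------

gb_tanh <- function(a) {
  a <- gb_wrap(a)
  v <- tanh(a$val)
  gb_node(v, list(a), function(g) list(g * (1 - v^2)))
}

gb_sigmoid <- function(a) {
  a <- gb_wrap(a)
  v <- 1 / (1 + exp(-a$val))
  gb_node(v, list(a), function(g) list(g * v * (1 - v)))
}

gb_relu <- function(a) {
  a <- gb_wrap(a)
  v <- a$val
  mask <- v > 0
  v[!mask] <- 0
  gb_node(v, list(a), function(g) list(g * mask))
}

gb_exp <- function(a) {
  a <- gb_wrap(a)
  v <- exp(a$val)
  gb_node(v, list(a), function(g) list(g * v))
}

# -- shape manipulation ------------------------------------------------------

gb_cbind <- function(nodes) {
  nodes <- lapply(nodes, gb_wrap)
  widths <- vapply(nodes, function(n) ncol(n$val), integer(1))
  val <- do.call(cbind, lapply(nodes, function(n) n$val))
  ends <- cumsum(widths)
  starts <- c(1L, head(ends, -1L) + 1L)
  gb_node(val, nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

gb_rbind <- function(nodes) {
  nodes <- lapply(nodes, gb_wrap)
  heights <- vapply(nodes, function(n) nrow(n$val), integer(1))
  val <- do.call(rbind, lapply(nodes, function(n) n$val))
  ends <- cumsum(heights)
  starts <- c(1L, head(ends, -1L) + 1L)
  gb_node(val, nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

gb_rows <- function(a, idx) {
  a <- gb_wrap(a)
  gb_node(a$val[idx, , drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$val), ncol(a$val))
    out[idx, ] <- g
    list(out)
  })
}

gb_cols <- function(a, idx) {
  a <- gb_wrap(a)
  gb_node(a$val[, idx, drop = FALSE], list(a), function(g) {
    out <- matrix(0, nrow(a$val), ncol(a$val))
    out[, idx] <- g
    list(out)
  })
}

gb_sum_list <- function(nodes) {
  nodes <- lapply(nodes, gb_wrap)
  val <- nodes[[1L]]$val
  if (length(nodes) > 1L) for (i in 2:length(nodes)) val <- val + nodes[[i]]$val
  gb_node(val, nodes, function(g) rep(list(g), length(nodes)))
}

# Row-wise inner product: returns an (n x 1) column of sum(a_i * b_i).
gb_rowdot <- function(a, b) {
  a <- gb_wrap(a); b <- gb_wrap(b)
  v <- matrix(rowSums(a$val * b$val), ncol = 1L)
  gb_node(v, list(a, b), function(g) {
    gv <- as.vector(g)
    list(a = b$val * gv, b = a$val * gv)
  })
}

# -- batch normalization -----------------------------------------------------

# Column-wise batch normalization over the rows of a batch-stacked matrix.
# `stats` is an environment carrying running mean/var (momentum update in
# training mode); gamma and beta are 1 x C parameter nodes.
gb_batchnorm <- function(a, gamma, beta, stats, training, momentum = 0.1,
                         eps = 1e-5) {
  a <- gb_wrap(a)
  n <- nrow(a$val)
  if (training) {
    mu <- colMeans(a$val)
    va <- colMeans(sweep(a$val, 2L, mu)^2)
    if (is.null(stats$mean)) {
      stats$mean <- mu
      stats$var <- va
    } else {
      stats$mean <- (1 - momentum) * stats$mean + momentum * mu
      stats$var <- (1 - momentum) * stats$var + momentum * va
    }
  } else {
    mu <- stats$mean
    va <- stats$var
    if (is.null(mu)) { mu <- rep(0, ncol(a$val)); va <- rep(1, ncol(a$val)) }
  }
  sd_ <- sqrt(va + eps)
  xhat <- sweep(sweep(a$val, 2L, mu), 2L, sd_, "/")
  gv <- gb_bcast(gamma$val, 1L, ncol(a$val))
  bv <- gb_bcast(beta$val, 1L, ncol(a$val))
  val <- sweep(xhat, 2L, as.vector(gv), "*")
  val <- sweep(val, 2L, as.vector(bv), "+")
  gb_node(val, list(a, gamma, beta), function(g) {
    g_gamma <- matrix(colSums(g * xhat), 1L)
    g_beta <- matrix(colSums(g), 1L)
    gx <- sweep(g, 2L, as.vector(gv), "*")
    if (training) {
      # standard batch-norm backward through batch statistics
      gxh_sum <- colSums(gx)
      gxx_sum <- colSums(gx * xhat)
      ga <- sweep(
        gx - matrix(gxh_sum / n, n, length(gxh_sum), byrow = TRUE) -
          xhat * matrix(gxx_sum / n, n, length(gxx_sum), byrow = TRUE),
        2L, sd_, "/")
    } else {
      ga <- sweep(gx, 2L, sd_, "/")
    }
    list(ga, g_gamma, g_beta)
  })
}

# -- losses ------------------------------------------------------------------

#' Mean-absolute-error loss node
#' @keywords internal
gb_loss_mae <- function(pred, target) {
  pred <- gb_wrap(pred)
  tv <- gb_value(target)
  d <- pred$val - tv
  val <- matrix(mean(abs(d)), 1L, 1L)
  gb_node(val, list(pred), function(g) {
    list(sign(d) * (g[1L] / length(d)))
  })
}

# -- backward sweep ----------------------------------------------------------

#' Run the reverse sweep from a scalar loss node
#'
#' Accumulates gradients into the `grad` field of every reachable parameter
#' node (overwriting previous contents).
#' @keywords internal
gb_backward <- function(loss) {
  stopifnot(gb_is_node(loss), length(loss$val) == 1L)
  # collect reachable nodes that need gradients
  seen <- new.env(hash = TRUE, parent = emptyenv())
  nodes <- list()
  stack <- list(loss)
  while (length(stack)) {
    nd <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    key <- as.character(nd$pid)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) if (p$needs) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, function(n) n$pid, integer(1)),
               decreasing = TRUE)
  nodes <- nodes[ord]
  grads <- new.env(hash = TRUE, parent = emptyenv())
  grads[[as.character(loss$pid)]] <- matrix(1, 1L, 1L)
  for (nd in nodes) {
    g <- grads[[as.character(nd$pid)]]
    if (is.null(g)) next
    if (nd$is_param) {
      nd$grad <- if (is.null(nd$grad)) g else nd$grad + g
    }
    if (is.null(nd$vjp)) next
    pgrads <- nd$vjp(g)
    for (i in seq_along(nd$parents)) {
      p <- nd$parents[[i]]
      if (!p$needs) next
      pg <- pgrads[[i]]
      if (is.null(pg)) next
      key <- as.character(p$pid)
      cur <- grads[[key]]
      grads[[key]] <- if (is.null(cur)) pg else cur + pg
    }
  }
  invisible(NULL)
}

#' Zero the stored gradients of a list of parameter nodes
#' @keywords internal
gb_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}
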