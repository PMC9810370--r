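# Transition operators and graph convolutions.
#
# Spatial mixing is modeled as a random-walk diffusion: the weighted
# adjacency A is row-normalized into a transition operator T = D^-1 A, and a
# graph filter is the truncated power series sum_k theta_k T^k applied to the
# node signal. An optional learned adaptive adjacency tanh(V)/N can replace
# or complement T.

#' Construct a weighted adjacency
#'
#' @param weights N x N nonnegative matrix; for `"SC"` and `"synthetic"`
#'   kinds the matrix must be symmetric (within 1e-9). Correlation-derived
#'   `"CE"` matrices may carry negative entries; these are handled at
#'   transition-operator construction.
#' @param kind one of `"SC"`, `"CE"`, `"synthetic"`
#' @return a `weighted_adjacency`
#' @export
weighted_adjacency <- function(weights, kind = c("SC", "CE", "synthetic")) {
  kind <- match.arg(kind)
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) stop("adjacency must be square")
  if (any(!is.finite(weights))) stop("adjacency entries must be finite")
  if (kind != "CE" && max(abs(weights - t(weights))) > 1e-9)
    stop("SC/synthetic adjacency must be symmetric")
  if (kind != "CE" && any(weights < 0))
    stop("SC/synthetic adjacency must be nonnegative")
  structure(list(weights = weights, kind = kind),
            class = "weighted_adjacency")
}

#' @export
print.weighted_adjacency <- function(x, ...) {
  cat(sprintf("<weighted_adjacency (%s): %d x %d, %d nonzero entries>\n",
              x$kind, nrow(x$weights), ncol(x$weights),
              sum(x$weights != 0)))
  invisible(x)
}

#' Row-stochastic transition operator T = D^-1 A
#'
#' Node degrees are the row sums of the (clipped) weights; rows with positive
#' degree are normalized to sum to 1, zero-degree rows stay all-zero so an
#' isolated node only ever receives its own walk-order-0 contribution.
#' Negative entries (possible in correlation-based CE adjacencies) are
#' clipped to zero by default, or replaced by their absolute value with
#' `negative = "absolute"`.
#'
#' @param adj a [weighted_adjacency()] or bare nonnegative matrix
#' @param negative how to treat negative weights: `"clip"` (default),
#'   `"absolute"`, or `"error"`
#' @return a `transition_operator` with fields `T` (N x N matrix) and
#'   `degree`
#' @export
transition_matrix <- function(adj, negative = c("clip", "absolute", "error")) {
  negative <- match.arg(negative)
  w <- if (inherits(adj, "weighted_adjacency")) adj$weights else as.matrix(adj)
  if (any(w < 0)) {
    w <- switch(negative,
      clip = pmax(w, 0),
      absolute = abs(w),
      error = stop("adjacency has negative weights"))
  }
  deg <- rowSums(w)
  tm <- w
  pos <- deg > 0
  tm[pos, ] <- w[pos, , drop = FALSE] / deg[pos]
  tm[!pos, ] <- 0
  structure(list(T = tm, degree = deg), class = "transition_operator")
}

#' @export
print.transition_operator <- function(x, ...) {
  cat(sprintf("<transition_operator: %d nodes, %d with positive degree>\n",
              nrow(x$T), sum(x$degree > 0)))
  invisible(x)
}

#' Diffusion-convolution filter coefficients
#'
#' @param theta coefficient array of shape (K+1, Q, M): walk order k = 0..K,
#'   output channel q, input channel m
#' @param activation scalar nonlinearity applied after the power series:
#'   `"identity"`, `"relu"`, `"tanh"`, or `"sigmoid"`
#' @return a `diffusion_filter`
#' @export
diffusion_filter <- function(theta, activation = c("identity", "relu",
                                                   "tanh", "sigmoid")) {
  activation <- match.arg(activation)
  theta <- as.array(theta)
  if (length(dim(theta)) == 1L) theta <- array(theta, c(length(theta), 1L, 1L))
  if (length(dim(theta)) == 2L) theta <- array(theta, c(dim(theta), 1L))
  stopifnot(length(dim(theta)) == 3L)
  structure(list(theta = theta, K = dim(theta)[1L] - 1L,
                 activation = activation),
            class = "diffusion_filter")
}

gb_activation <- function(name) {
  switch(name,
    identity = identity,
    relu = function(x) pmax(x, 0),
    tanh = tanh,
    sigmoid = function(x) 1 / (1 + exp(-x)))
}

#' Diffusion convolution y^q = sum_m sum_k theta_k^{qm} T^k x^m
#'
#' Powers of the operator are never materialized: `T^k x` is computed by k
#' repeated products, so the cost is linear in edges times K.
#'
#' @param x node signal, N x M matrix (columns are input channels)
#' @param op a [transition_matrix()] result or bare operator matrix
#' @param filter a [diffusion_filter()]
#' @return N x Q matrix of filtered (and activated) output channels
#' @export
diffusion_convolution <- function(x, op, filter) {
  tm <- if (inherits(op, "transition_operator")) op$T else as.matrix(op)
  x <- as.matrix(x)
  if (nrow(x) != nrow(tm)) stop("x must have one row per node")
  th <- filter$theta
  if (dim(th)[3L] != ncol(x))
    stop(sprintf("filter expects %d input channels, got %d",
                 dim(th)[3L], ncol(x)))
  kmax <- filter$K
  q <- dim(th)[2L]
  out <- matrix(0, nrow(x), q)
  tkx <- x
  for (k in 0:kmax) {
    if (k > 0L) tkx <- tm %*% tkx
    out <- out + tkx %*% t(matrix(th[k + 1L, , ], q, ncol(x)))
  }
  gb_activation(filter$activation)(out)
}

#' Normalized self-adaptive adjacency tanh(V) / N
#'
#' @param v unconstrained square matrix of trainable weights
#' @return N x N matrix with entries strictly inside (-1/N, 1/N)
#' @export
adaptive_adjacency <- function(v) {
  v <- as.matrix(v)
  if (nrow(v) != ncol(v)) stop("V must be square")
  tanh(v) / nrow(v)
}

#' Hybrid graph convolution over diffusion and adaptive operators
#'
#' Sums the two operator families' power series before the activation:
#' `y^q = sum_k (theta_k^q T^k + theta_k^{q,Adap} A_adap^k) x`. With the
#' adaptive operator absent this reduces to [diffusion_convolution()]; with
#' the transition operator absent it is the adaptive-only variant.
#'
#' @param x node signal, N x M
#' @param op transition operator (or NULL)
#' @param a_adap adaptive adjacency matrix (or NULL)
#' @param filter [diffusion_filter()] for the diffusion branch
#' @param filter_adap [diffusion_filter()] for the adaptive branch (defaults
#'   to `filter`'s shape requirement; required when `a_adap` is given)
#' @param activation overrides the filter's activation when given
#' @return N x Q matrix
#' @export
graph_conv_hybrid <- function(x, op = NULL, a_adap = NULL, filter = NULL,
                              filter_adap = NULL, activation = NULL) {
  if (is.null(op) && is.null(a_adap))
    stop("at least one of the transition or adaptive operator is required")
  x <- as.matrix(x)
  act_name <- activation %||%
    (if (!is.null(filter)) filter$activation else filter_adap$activation)
  pre <- matrix(0, nrow(x),
                if (!is.null(filter)) dim(filter$theta)[2L]
                else dim(filter_adap$theta)[2L])
  accumulate <- function(opm, flt) {
    th <- flt$theta
    q <- dim(th)[2L]
    acc <- matrix(0, nrow(x), q)
    tkx <- x
    for (k in 0:flt$K) {
      if (k > 0L) tkx <- opm %*% tkx
      acc <- acc + tkx %*% t(matrix(th[k + 1L, , ], q, ncol(x)))
    }
    acc
  }
  if (!is.null(op)) {
    tm <- if (inherits(op, "transition_operator")) op$T else as.matrix(op)
    pre <- pre + accumulate(tm, filter)
  }
  if (!is.null(a_adap)) {
    if (is.null(filter_adap)) stop("filter_adap required with a_adap")
    pre <- pre + accumulate(as.matrix(a_adap), filter_adap)
  }
  gb_activation(act_name)(pre)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
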