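# Forecast evaluation metrics: MAE, per-horizon MAE, pooled R-squared, and
# functional-connectivity state similarity.

#' Mean absolute error
#'
#' Average of absolute differences over regions, horizon steps, and (when 3-d
#' arrays are supplied) samples.
#'
#' @param x_true,x_pred numeric matrices (N x T) or arrays (N x T x S) of
#'   identical shape
#' @return scalar MAE
#' @export
mae <- function(x_true, x_pred) {
  if (!identical(dim(as.array(x_true)), dim(as.array(x_pred))))
    stop("shape mismatch between truth and prediction")
  mean(abs(x_true - x_pred))
}

#' Per-horizon-step MAE
#'
#' @inheritParams mae
#' @return numeric vector of length T (the horizon); its mean equals
#'   [mae()]
#' @export
horizon_mae <- function(x_true, x_pred) {
  xt <- as.array(x_true); xp <- as.array(x_pred)
  if (!identical(dim(xt), dim(xp)))
    stop("shape mismatch between truth and prediction")
  d <- abs(xt - xp)
  if (length(dim(d)) == 2L) colMeans(d)
  else apply(d, 2L, mean)
}

#' Pooled R-squared
#'
#' `1 - SS_res / SS_tot` pooled over all regions, horizon steps and samples.
#' `per_region = TRUE` instead returns one value per region (pooling over
#' time and samples within the region).
#'
#' @inheritParams mae
#' @param per_region return a per-region vector instead of the pooled scalar
#' @export
r_squared <- function(x_true, x_pred, per_region = FALSE) {
  xt <- as.array(x_true); xp <- as.array(x_pred)
  if (!identical(dim(xt), dim(xp)))
    stop("shape mismatch between truth and prediction")
  if (per_region) {
    n <- dim(xt)[1L]
    vapply(seq_len(n), function(i) {
      ti <- if (length(dim(xt)) == 2L) xt[i, ] else xt[i, , ]
      pi <- if (length(dim(xt)) == 2L) xp[i, ] else xp[i, , ]
      if (stats::var(as.vector(ti)) == 0) stop("constant truth series")
      1 - sum((ti - pi)^2) / sum((ti - mean(ti))^2)
    }, numeric(1))
  } else {
    if (stats::var(as.vector(xt)) == 0)
      stop("constant truth; R-squared undefined")
    1 - sum((xt - xp)^2) / sum((xt - mean(xt))^2)
  }
}

#' Functional-connectivity state of a signal block
#'
#' The FC state is the N x N matrix of pairwise Pearson correlations of the
#' region time courses.
#'
#' @param signals N x T matrix with T >= 3
#' @return an `fc_state`: list with the correlation matrix `A_fc`
#' @export
fc_state <- function(signals) {
  signals <- as.matrix(signals)
  if (ncol(signals) < 3L) stop("need at least 3 time points for an FC state")
  sds <- apply(signals, 1L, stats::sd)
  if (any(sds == 0)) stop("constant region series; correlation undefined")
  structure(list(A_fc = stats::cor(t(signals))), class = "fc_state")
}

#' Similarity between predicted and true FC states
#'
#' Pearson correlation between the strictly upper-triangular entries of the
#' two FC matrices (the diagonal is uninformative ones).
#'
#' @param pred,true N x T signal matrices, or `fc_state` objects
#' @return scalar r_FC
#' @export
fc_similarity <- function(pred, true) {
  ap <- if (inherits(pred, "fc_state")) pred$A_fc else fc_state(pred)$A_fc
  at <- if (inherits(true, "fc_state")) true$A_fc else fc_state(true)$A_fc
  ut <- upper.tri(ap)
  stats::cor(ap[ut], at[ut])
}
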