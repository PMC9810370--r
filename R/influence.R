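# Perturbation-based directed influence: silence one region's input window,
# forecast, and measure the mean absolute change in every region's
# prediction.

#' Silence one region in a window sample
#'
#' Replaces the region's past sequence by zeros (the sample mean of
#' standardized data); the future block and all other regions are untouched.
#' A warning is raised when the data do not look standardized (region mean
#' far from zero), since the perturbation is then not a mean-replacement.
#'
#' @param sample list with `past` and `future` (as from [window_sample()])
#' @param region region index to silence
#' @param tol mean-magnitude threshold for the standardization warning
#' @return the perturbed sample
#' @export
perturb_sample <- function(sample, region, tol = 0.5) {
  if (abs(mean(sample$past[region, ])) > tol &&
      abs(mean(sample$past)) > tol)
    warning("input does not look standardized; zeroing is not a mean-replacement")
  sample$past[region, ] <- 0
  sample
}

# zero one region across a batch array (N x t_p x B)
gb_perturb_batch <- function(past, region) {
  past[region, , ] <- 0
  past
}

#' Directed influence of one source region
#'
#' `I_n(n') = 1/S sum_s 1/T_f sum_t |xhat - xhat'|`: the mean absolute
#' difference between the unperturbed forecast and the forecast with region
#' `region`'s input silenced, per target region, averaged over horizon and
#' samples.
#'
#' @param model a fitted forecaster
#' @param w `gb_windows` with the evaluation samples (typically the test
#'   split)
#' @param region source region n' to silence
#' @param base_pred optional precomputed unperturbed predictions (array
#'   N x t_f x S) to avoid recomputation across regions
#' @param batch_size forward-pass batch size
#' @return numeric vector of length N: influence of `region` on every
#'   target region
#' @export
influence_vector <- function(model, w, region, base_pred = NULL,
                             batch_size = 64L) {
  nw <- n_windows(w)
  if (nw == 0L) stop("no evaluation samples")
  if (is.null(base_pred)) base_pred <- predict_windows(model, w, batch_size)$pred
  chunks <- split(seq_len(nw), ceiling(seq_len(nw) / batch_size))
  acc <- NULL
  for (idx in chunks) {
    b <- window_batch(w, idx)
    pert <- forecast(model, gb_perturb_batch(b$past, region), t_f = w$t_f)
    d <- abs(base_pred[, , idx, drop = FALSE] - pert)
    contrib <- apply(d, 1L, sum)
    acc <- if (is.null(acc)) contrib else acc + contrib
  }
  acc / (nw * w$t_f)
}

#' Full directed-influence matrix
#'
#' Systematically silences every source region (or the subset `targets`)
#' and records the effect on all regions. Entry (n, n') is the influence of
#' source n' on target n; columns follow the region order.
#'
#' @inheritParams influence_vector
#' @param targets source regions to perturb (default all)
#' @return an `influence_matrix`: list with `I` (N x N matrix, columns =
#'   sources), `S` (sample count), `t_f`, `rescaled`
#' @export
influence_matrix <- function(model, w, targets = NULL, batch_size = 64L) {
  base_pred <- predict_windows(model, w, batch_size)$pred
  n <- dim(base_pred)[1L]
  targets <- targets %||% seq_len(n)
  im <- matrix(0, n, n)
  for (src in targets)
    im[, src] <- influence_vector(model, w, src, base_pred = base_pred,
                                  batch_size = batch_size)
  structure(list(I = im, S = n_windows(w), t_f = w$t_f, targets = targets,
                 rescaled = FALSE),
            class = "influence_matrix")
}

#' @export
print.influence_matrix <- function(x, ...) {
  cat(sprintf("<influence_matrix: %d x %d, %d samples, horizon %d%s>\n",
              nrow(x$I), ncol(x$I), x$S, x$t_f,
              if (x$rescaled) ", rescaled 0-100" else ""))
  invisible(x)
}

#' Rescale an influence matrix to the 0-100 range
#'
#' Linear map sending the off-diagonal minimum to 0 and maximum to 100.
#' Diagonal (self-influence) entries are excluded from the statistics and
#' set to NA in the rescaled matrix.
#'
#' @param im an [influence_matrix()]
#' @return the rescaled `influence_matrix`
#' @export
rescale_0_100 <- function(im) {
  stopifnot(inherits(im, "influence_matrix"))
  m <- im$I
  off <- m[row(m) != col(m)]
  lo <- min(off); hi <- max(off)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi)))
    stop("constant off-diagonal influence; rescaling is degenerate")
  out <- (m - lo) / (hi - lo) * 100
  diag(out) <- NA_real_
  im$I <- out
  im$rescaled <- TRUE
  im
}

#' Edge-recovery AUC of an influence matrix
#'
#' Ranks off-diagonal influence entries and asks how well true edges of a
#' reference graph separate from non-edges (Mann-Whitney AUC via the
#' rank-sum statistic).
#'
#' @param im an [influence_matrix()] (raw or rescaled)
#' @param graph the reference [weighted_adjacency()] (nonzero = edge)
#' @return AUC in \[0, 1\]
#' @export
influence_edge_auc <- function(im, graph) {
  a <- if (inherits(graph, "weighted_adjacency")) graph$weights else graph
  off <- row(a) != col(a)
  labels <- a[off] > 0
  scores <- im$I[off]
  if (!any(labels) || all(labels)) stop("need both edges and non-edges")
  r <- rank(scores)
  n1 <- sum(labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * sum(!labels))
}

#' Write an influence matrix as delimited text
#' @param im an `influence_matrix`
#' @param path output file
#' @param regions optional region labels for row/column names
#' @param sep field separator
#' @export
write_influence <- function(im, path, regions = NULL, sep = "\t") {
  m <- im$I
  if (!is.null(regions)) dimnames(m) <- list(regions, regions)
  utils::write.table(m, path, sep = sep, quote = FALSE,
                     row.names = !is.null(regions),
                     col.names = !is.null(regions))
  invisible(path)
}
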