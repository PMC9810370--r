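# Vector-autoregression baseline: pooled OLS fit, recursive multi-step
# forecasting, order selection by test MAE, and an augmented Dickey-Fuller
# stationarity screen.

#' Fit a VAR(p) by ordinary least squares
#'
#' One pooled model is fitted across all training data. Input can be a
#' `session_ts`, a list of them, or a `gb_windows` training split; for
#' windows the regression rows are built from the contiguous stretch of each
#' session covered by its training windows, so session boundaries are never
#' crossed.
#'
#' @param x training data (see above)
#' @param p autoregressive order (p = 0 fits the intercept-only model)
#' @return a `var_model` with coefficient matrices `A` (list of p N x N
#'   matrices), intercept `b`, order `p`, and residual summary
#' @export
fit_var <- function(x, p) {
  p <- as.integer(p)
  if (p < 0L) stop("order must be nonnegative")
  segments <- gb_var_segments(x)
  n <- nrow(segments[[1L]])
  rows_y <- list(); rows_x <- list()
  for (seg in segments) {
    tt <- ncol(seg)
    if (tt <= p) next
    idx <- (p + 1L):tt
    rows_y[[length(rows_y) + 1L]] <- t(seg[, idx, drop = FALSE])
    if (p > 0L) {
      lagged <- lapply(seq_len(p), function(l) t(seg[, idx - l, drop = FALSE]))
      rows_x[[length(rows_x) + 1L]] <- do.call(cbind, lagged)
    }
  }
  if (!length(rows_y)) stop("insufficient samples to fit VAR")
  y <- do.call(rbind, rows_y)
  if (p == 0L) {
    b <- colMeans(y)
    resid <- sweep(y, 2L, b)
    return(structure(list(p = 0L, A = list(), b = b, n = n,
                          sigma = apply(resid, 2L, stats::sd)),
                     class = "var_model"))
  }
  xm <- cbind(1, do.call(rbind, rows_x))
  if (nrow(xm) <= ncol(xm))
    stop(sprintf("insufficient samples: %d rows for %d coefficients",
                 nrow(xm), ncol(xm)))
  qrx <- qr(xm)
  if (qrx$rank < ncol(xm)) stop("rank-deficient regression design")
  beta <- qr.coef(qrx, y)                      # (1 + N*p) x N
  b <- beta[1L, ]
  a_list <- lapply(seq_len(p), function(l) {
    t(beta[1L + (l - 1L) * n + seq_len(n), , drop = FALSE])
  })
  resid <- y - xm %*% beta
  structure(list(p = p, A = a_list, b = b, n = n,
                 sigma = apply(resid, 2L, stats::sd)),
            class = "var_model")
}

# contiguous per-session training segments for the regression design
gb_var_segments <- function(x) {
  if (inherits(x, "session_ts")) return(list(x$values))
  if (inherits(x, "gb_windows")) {
    return(lapply(Filter(function(s) length(s$starts) > 0L, x$sessions),
                  function(s) {
      lo <- min(s$starts)
      hi <- max(s$starts) + x$t_p + x$t_f - 1L
      s$values[, lo:hi, drop = FALSE]
    }))
  }
  if (is.list(x)) return(lapply(x, function(s) {
    stopifnot(inherits(s, "session_ts")); s$values
  }))
  stop("unsupported input for fit_var")
}

#' @export
print.var_model <- function(x, ...) {
  cat(sprintf("<var_model: N = %d, p = %d, %d parameters>\n",
              x$n, x$p, x$n * x$n * x$p + x$n))
  invisible(x)
}

#' Tidy VAR coefficients
#' @param x a `var_model`
#' @param ... unused
#' @return tibble with one row per coefficient (lag, target, source,
#'   estimate); lag 0 rows carry the intercept
#' @export
tidy.var_model <- function(x, ...) {
  rows <- list(tibble::tibble(lag = 0L, target = seq_len(x$n),
                              source = NA_integer_, estimate = x$b))
  for (l in seq_len(x$p)) {
    a <- x$A[[l]]
    rows[[l + 1L]] <- tibble::tibble(
      lag = l,
      target = rep(seq_len(x$n), times = x$n),
      source = rep(seq_len(x$n), each = x$n),
      estimate = as.vector(a))
  }
  do.call(rbind, rows)
}

#' One-line VAR summary
#' @param x a `var_model`
#' @param ... unused
#' @export
glance.var_model <- function(x, ...) {
  tibble::tibble(n_regions = x$n, order = x$p,
                 n_parameters = x$n * x$n * x$p + x$n,
                 mean_resid_sd = mean(x$sigma))
}

#' Recursive multi-step VAR forecast
#'
#' Applies the fitted recursion `x_t = b + sum_l A_l x_{t-l}` for `t_f`
#' steps, each prediction feeding the next.
#'
#' @param model a [fit_var()] result
#' @param history N x >= p matrix of most recent observations (latest column
#'   last)
#' @param t_f number of steps to forecast
#' @return N x t_f matrix of predictions
#' @export
forecast_var <- function(model, history, t_f) {
  history <- as.matrix(history)
  if (ncol(history) < model$p)
    stop(sprintf("history has %d columns; order-%d model needs at least %d",
                 ncol(history), model$p, model$p))
  n <- model$n
  buf <- history
  out <- matrix(0, n, t_f)
  for (s in seq_len(t_f)) {
    xt <- model$b
    for (l in seq_len(model$p))
      xt <- xt + model$A[[l]] %*% buf[, ncol(buf) - l + 1L]
    out[, s] <- xt
    buf <- cbind(buf, xt)
  }
  out
}

#' Forecast every window of a split with a VAR model
#' @param model a `var_model`
#' @param w a `gb_windows` (typically the test split)
#' @return list with arrays `pred` and `true`, each N x t_f x n_windows
#' @export
forecast_var_windows <- function(model, w) {
  nw <- n_windows(w)
  if (nw == 0L) stop("no windows to forecast")
  n <- model$n
  pred <- array(0, c(n, w$t_f, nw))
  true <- array(0, c(n, w$t_f, nw))
  for (i in seq_len(nw)) {
    s <- window_sample(w, i)
    pred[, , i] <- forecast_var(model, s$past, w$t_f)
    true[, , i] <- s$future
  }
  list(pred = pred, true = true)
}

#' Select the VAR order by test MAE
#'
#' Fits a candidate VAR(p) on the training split for every order in
#' `candidates` (by convention steps of five up to the input-window length),
#' forecasts the evaluation split, and returns the order with the lowest
#' MAE. Candidates with too few training samples are skipped with a warning.
#'
#' @param splits list with `train` and `test` (or `val`) `gb_windows`
#' @param candidates integer vector of orders to try
#' @param eval_split which split to score (`"test"` matches the selection
#'   convention used alongside the neural models)
#' @return list with `best_p` and `table` (tibble of order, mae)
#' @export
select_order <- function(splits, candidates = seq(5L, 60L, by = 5L),
                         eval_split = "test") {
  evw <- splits[[eval_split]]
  rows <- lapply(candidates, function(p) {
    model <- tryCatch(fit_var(splits$train, p), error = function(e) NULL)
    if (is.null(model)) {
      warning(sprintf("order p = %d infeasible; skipped", p))
      return(tibble::tibble(p = p, mae = NA_real_))
    }
    fc <- forecast_var_windows(model, evw)
    tibble::tibble(p = p, mae = mae(fc$true, fc$pred))
  })
  tab <- do.call(rbind, rows)
  if (all(is.na(tab$mae))) stop("no feasible VAR order candidate")
  list(best_p = tab$p[which.min(tab$mae)], table = tab)
}

#' Augmented Dickey-Fuller stationarity screen
#'
#' Fraction of region series for which the ADF test (with constant, lag
#' order chosen by AIC up to the Schwert rule) fails to reject a unit root
#' at level `alpha`. The test regression is
#' `diff(x)_t ~ 1 + x_{t-1} + diff(x)_{t-1..k}`, with the t-statistic on the
#' level term compared against MacKinnon finite-sample critical values.
#' Screening is reported, never blocking.
#'
#' @param x a `session_ts` or list of them
#' @param alpha significance level (default 0.01)
#' @return fraction in \[0, 1\] of nonstationary region series
#' @export
adf_fraction <- function(x, alpha = 0.01) {
  sessions <- if (inherits(x, "session_ts")) list(x) else x
  flags <- unlist(lapply(sessions, function(s) {
    apply(s$values, 1L, function(row) !gb_adf_reject(row, alpha))
  }))
  mean(flags)
}

# single-series ADF test with drift; returns TRUE when the unit root is
# rejected (series deemed stationary)
gb_adf_reject <- function(y, alpha = 0.01) {
  tt <- length(y)
  if (tt < 25L) stop("series too short for the ADF regression")
  kmax <- max(1L, floor(12 * (tt / 100)^0.25))
  dy <- diff(y)
  best <- NULL
  for (k in 0:kmax) {
    n_eff <- length(dy) - k
    yl <- y[(k + 1L):(tt - 1L)]
    dv <- dy[(k + 1L):length(dy)]
    xm <- cbind(1, yl)
    if (k > 0L)
      for (l in seq_len(k)) xm <- cbind(xm, dy[(k + 1L - l):(length(dy) - l)])
    fit <- stats::lm.fit(xm, dv)
    rss <- sum(fit$residuals^2)
    aic <- n_eff * log(rss / n_eff) + 2 * ncol(xm)
    if (is.null(best) || aic < best$aic) best <- list(aic = aic, fit = fit,
                                                     xm = xm, n = n_eff)
  }
  fit <- best$fit
  sigma2 <- sum(fit$residuals^2) / (best$n - ncol(best$xm))
  xtxinv <- chol2inv(chol(crossprod(best$xm)))
  tstat <- fit$coefficients[2L] / sqrt(sigma2 * xtxinv[2L, 2L])
  tstat < gb_adf_critical(best$n, alpha)
}

# MacKinnon (2010) response-surface critical values, constant-only case
gb_adf_critical <- function(n, alpha) {
  tab <- list(
    "0.01" = c(-3.43035, -6.5393, -16.786, -79.433),
    "0.05" = c(-2.86154, -2.8903, -4.234, -40.040),
    "0.1"  = c(-2.56677, -1.5384, -2.809, 0))
  key <- as.character(alpha)
  if (is.null(tab[[key]]))
    stop("alpha must be one of 0.01, 0.05, 0.1")
  b <- tab[[key]]
  b[1L] + b[2L] / n + b[3L] / n^2 + b[4L] / n^3
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")
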