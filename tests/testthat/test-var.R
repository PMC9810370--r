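# VAR baseline: OLS fit, recursive forecasting, order selection and the
# stationarity screen.

test_that("OLS recovers a diagonal VAR(1) and degenerate fits error", {
  set.seed(1)
  n <- 3; tt <- 5000
  x <- matrix(0, n, tt)
  for (t in 2:tt) x[, t] <- 0.5 * x[, t - 1] + rnorm(n, sd = 0.1)
  m <- fit_var(session_ts(x, 0.72, "ar"), p = 1)
  expect_lt(max(abs(diag(m$A[[1]]) - 0.5)), 0.05)
  expect_lt(max(abs(m$A[[1]][row(m$A[[1]]) != col(m$A[[1]])])), 0.05)
  # p = 0 reduces to the sample mean
  m0 <- fit_var(session_ts(x, 0.72, "ar"), p = 0)
  expect_equal(m0$b, rowMeans(x[, , drop = FALSE]), tolerance = 1e-12)
  # too few samples for the design
  short <- session_ts(matrix(rnorm(3 * 6), 3, 6), 0.72, "short")
  expect_error(fit_var(short, p = 2), "insufficient")
})

test_that("OLS residuals are orthogonal to the regressors", {
  set.seed(2)
  x <- matrix(rnorm(4 * 400), 4, 400)
  m <- fit_var(session_ts(x, 0.72, "n"), p = 2)
  # rebuild design and residuals
  y <- t(x[, 3:400])
  xm <- cbind(1, t(x[, 2:399]), t(x[, 1:398]))
  beta <- rbind(m$b, t(m$A[[1]]), t(m$A[[2]]))
  resid <- y - xm %*% beta
  expect_lt(max(abs(crossprod(xm, resid))) / nrow(xm), 1e-6)
})

test_that("recursive forecasts follow the fitted recursion exactly", {
  m <- structure(list(p = 1, A = list(matrix(0, 2, 2)), b = c(3, -1), n = 2),
                 class = "var_model")
  expect_equal(forecast_var(m, matrix(0, 2, 1), 3),
               matrix(c(3, -1), 2, 3))
  # univariate alpha = 1: random-walk persistence
  m1 <- structure(list(p = 1, A = list(matrix(1, 1, 1)), b = 0, n = 1),
                  class = "var_model")
  expect_equal(forecast_var(m1, matrix(4.2), 5), matrix(4.2, 1, 5))
  # univariate alpha = 0.5 from 1: (0.5, 0.25, 0.125)
  m5 <- structure(list(p = 1, A = list(matrix(0.5, 1, 1)), b = 0, n = 1),
                  class = "var_model")
  expect_equal(forecast_var(m5, matrix(1), 3),
               matrix(c(0.5, 0.25, 0.125), 1, 3))
  expect_error(forecast_var(m, matrix(0, 2, 0), 2), "history")
})

test_that("a noiseless linear system is reproduced exactly (self-consistency)", {
  set.seed(3)
  a <- matrix(rnorm(9, sd = 0.2), 3, 3)
  b <- rnorm(3)
  m <- structure(list(p = 1, A = list(a), b = b, n = 3),
                 class = "var_model")
  x0 <- rnorm(3)
  x <- matrix(0, 3, 21); x[, 1] <- x0
  for (t in 2:21) x[, t] <- b + a %*% x[, t - 1]
  expect_equal(forecast_var(m, x[, 1, drop = FALSE], 20), x[, 2:21],
               tolerance = 1e-10)
})

test_that("parameter count scales as N^2 p plus intercepts", {
  set.seed(4)
  x <- session_ts(matrix(rnorm(5 * 500), 5, 500), 0.72, "s")
  for (p in 1:3) {
    m <- fit_var(x, p)
    expect_length(m$A, p)
    n_par <- sum(vapply(m$A, length, numeric(1))) + length(m$b)
    expect_equal(n_par, 5^2 * p + 5)
  }
  expect_equal(glance(fit_var(x, 2))$n_parameters, 55)
})

test_that("order selection minimizes test MAE and prefers the true lag", {
  set.seed(5)
  hits <- 0
  for (seed in 1:5) {
    set.seed(seed)
    n <- 3; tt <- 500
    x <- matrix(0, n, tt)
    # strong lag-5 structure, weak lag-1; short series so that the extra
    # parameters of larger orders carry visible estimation noise
    for (t in 6:tt) x[, t] <- 0.15 * x[, t - 1] + 0.7 * x[, t - 5] +
        rnorm(n, sd = 0.5)
    prep <- prepare_data(list(session_ts(x, 0.72, "l5")), t_p = 15, t_f = 5,
                         scale_mode = "none")
    sel <- select_order(prep$splits, candidates = c(5L, 10L, 15L))
    expect_equal(sel$best_p, sel$table$p[which.min(sel$table$mae)])
    if (sel$best_p == 5L) hits <- hits + 1
  }
  expect_gte(hits, 4)
  # single feasible candidate is returned
  s <- session_ts(matrix(rnorm(2 * 120), 2, 120), 0.72, "one")
  prep1 <- prepare_data(list(s), t_p = 5, t_f = 5, scale_mode = "none")
  sel1 <- select_order(prep1$splits, candidates = 5L)
  expect_equal(sel1$best_p, 5L)
})

test_that("the ADF screen flags random walks but passes stationary series", {
  set.seed(6)
  rw_flagged <- 0; ar_passed <- 0
  for (seed in 1:20) {
    set.seed(seed)
    rw <- cumsum(rnorm(1000))
    ar <- as.vector(stats::arima.sim(list(ar = 0.2), 1000))
    if (adf_fraction(session_ts(matrix(rw, 1), 0.72, "rw")) == 1)
      rw_flagged <- rw_flagged + 1
    if (adf_fraction(session_ts(matrix(ar, 1), 0.72, "ar")) == 0)
      ar_passed <- ar_passed + 1
  }
  expect_gte(rw_flagged / 20, 0.95)
  expect_gte(ar_passed / 20, 0.95)
  # mixed session: fraction lies in [0, 1]
  set.seed(7)
  mixed <- session_ts(rbind(cumsum(rnorm(600)),
                            as.vector(stats::arima.sim(list(ar = 0.3), 600))),
                      0.72, "mix")
  f <- adf_fraction(mixed)
  expect_gte(f, 0); expect_lte(f, 1)
  expect_error(adf_fraction(session_ts(matrix(rnorm(10), 1), 0.72, "s")),
               "too short")
})

test_that("tidy and glance summarize a fitted VAR", {
  set.seed(8)
  x <- session_ts(matrix(rnorm(3 * 300), 3, 300), 0.72, "t")
  m <- fit_var(x, 2)
  td <- tidy(m)
  expect_equal(nrow(td), 3 + 2 * 9)
  expect_equal(td$estimate[td$lag == 1][1], m$A[[1]][1, 1])
  gl <- glance(m)
  expect_equal(gl$order, 2L)
})
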