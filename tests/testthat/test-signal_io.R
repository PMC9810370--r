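# Session containers, band-pass filtering, scaling, windowing and splits.

test_that("band-pass filter keeps in-band sinusoids and rejects out-of-band", {
  dt <- 0.72
  t_len <- 1200
  tt <- (seq_len(t_len) - 1) * dt
  in_band <- sin(2 * pi * 0.055 * tt)
  out_band <- sin(2 * pi * 0.2 * tt)
  s <- session_ts(rbind(in_band, out_band), dt, "sines")
  f <- bandpass_filter(s, 0.04, 0.07)
  # regress the filtered series onto the generating quadrature pair,
  # discarding edge transients
  keep <- 150:(t_len - 150)
  amp <- function(y, freq) {
    fit <- lm(y[keep] ~ sin(2 * pi * freq * tt[keep]) +
                cos(2 * pi * freq * tt[keep]))
    sqrt(sum(coef(fit)[2:3]^2))
  }
  expect_lt(abs(amp(f$values[1, ], 0.055) - 1), 0.05)
  expect_lt(amp(f$values[2, ], 0.2), 10^(-20 / 20))   # >= 20 dB down
})

test_that("filter maps zero to zero, is linear, and validates the band", {
  s <- session_ts(matrix(0, 2, 100), 0.72, "z")
  expect_equal(bandpass_filter(s)$values, matrix(0, 2, 100))
  set.seed(3)
  x <- matrix(rnorm(300), 3, 100)
  y <- matrix(rnorm(300), 3, 100)
  fx <- bandpass_filter(session_ts(x, 0.72, "x"))$values
  fy <- bandpass_filter(session_ts(y, 0.72, "y"))$values
  fxy <- bandpass_filter(session_ts(2 * x - 3 * y, 0.72, "xy"))$values
  # order-5 IIR recursions leave ~1e-7 of double-precision rounding
  expect_lt(max(abs(fxy - (2 * fx - 3 * fy))), 1e-6)
  expect_error(bandpass_filter(s, 0.04, 0.8), "invalid band")
  expect_error(bandpass_filter(s, -0.1, 0.07), "invalid band")
})

test_that("min-max scaling maps the session onto [0,1] and inverts exactly", {
  s <- session_ts(matrix(c(2, 3, 4, 2.5), 2, 2), 0.72, "mm")
  sc <- scale_signals(s, "minmax01")
  expect_equal(sc$data$values, (s$values - 2) / 2)
  expect_equal(min(sc$data$values), 0)
  expect_equal(max(sc$data$values), 1)
  back <- unscale_signals(sc$data, sc$params)
  expect_lt(max(abs(back$values - s$values)), 1e-10)
  const <- session_ts(matrix(5, 2, 10), 0.72, "const")
  expect_error(scale_signals(const, "minmax01"), "degenerate")
})

test_that("z-scoring pools per-region statistics over sessions and inverts", {
  sessions <- list(random_session(3, 40, 1), random_session(3, 60, 2))
  sc <- scale_signals(sessions, "zscore")
  pooled <- do.call(cbind, lapply(sc$data, `[[`, "values"))
  expect_lt(max(abs(rowMeans(pooled))), 1e-8)
  expect_lt(max(abs(apply(pooled, 1, var) - 1)), 1e-8)
  back <- unscale_signals(sc$data, sc$params)
  for (i in 1:2)
    expect_lt(max(abs(back[[i]]$values - sessions[[i]]$values)), 1e-10)
})

test_that("windowing count follows T - T_p - T_f + 1 with stride one", {
  # enumeration oracle over random shapes
  set.seed(42)
  for (i in 1:50) {
    t_p <- sample(1:6, 1); t_f <- sample(1:6, 1)
    t_len <- t_p + t_f + sample(0:30, 1)
    s <- random_session(2, t_len, seed = i)
    w <- make_windows(s, t_p, t_f)
    starts <- Filter(function(st) st + t_p + t_f - 1L <= t_len,
                     seq_len(t_len))
    expect_equal(n_windows(w), length(starts))
    expect_equal(n_windows(w), t_len - t_p - t_f + 1L)
  }
  s3 <- session_ts(matrix(1:3, 1), 0.72, "tiny")
  w3 <- make_windows(s3, 1, 1)
  expect_equal(n_windows(w3), 2L)
  expect_equal(window_sample(w3, 1)$past, matrix(1, 1, 1))
  expect_equal(window_sample(w3, 1)$future, matrix(2, 1, 1))
  expect_equal(window_sample(w3, 2)$past, matrix(2, 1, 1))
  expect_equal(window_sample(w3, 2)$future, matrix(3, 1, 1))
  expect_equal(n_windows(make_windows(random_session(2, 7), 3, 4)), 1L)
  expect_error(make_windows(random_session(2, 6), 3, 4), "too short")
})

test_that("windows are contiguous slices of the source series", {
  s <- random_session(3, 30, seed = 9)
  w <- make_windows(s, 4, 2)
  for (i in seq_len(n_windows(w))) {
    smp <- window_sample(w, i)
    expect_equal(cbind(smp$past, smp$future),
                 s$values[, smp$origin$start + 0:5, drop = FALSE])
  }
})

test_that("chronological split reproduces the 80/10/10 floor rule", {
  # a 1,200-step session windowed at 60/60 must yield 108 test pairs
  s <- random_session(1, 1200, seed = 2)
  w <- make_windows(s, 60, 60)
  expect_equal(n_windows(w), 1081L)
  sp <- split_windows(w)
  expect_equal(n_windows(sp$test), 108L)
  expect_equal(n_windows(sp$val), 108L)
  expect_equal(n_windows(sp$train), 865L)
  # 10 pairs -> 8 / 1 / 1
  s10 <- random_session(1, 11, seed = 3)
  sp10 <- split_windows(make_windows(s10, 1, 1))
  expect_equal(sapply(sp10, n_windows), c(train = 8L, val = 1L, test = 1L))
  # splits are chronological: max train start < min val start < min test start
  expect_lt(max(sp$train$sessions[[1]]$starts),
            min(sp$val$sessions[[1]]$starts))
  expect_lt(max(sp$val$sessions[[1]]$starts),
            min(sp$test$sessions[[1]]$starts))
  expect_error(split_windows(w, c(0.5, 0.5, 0.5)), "fractions")
})

test_that("session and adjacency round-trip through delimited files", {
  dir <- withr::local_tempdir()
  s <- random_session(3, 20, seed = 5)
  rownames(s$values) <- c("A", "B", "C")
  p <- file.path(dir, "sess.tsv")
  write_session(s, p)
  s2 <- read_session(p, session_id = "sess")
  expect_equal(unname(s2$values), unname(s$values))
  a <- make_graph(4, 0.5, seed = 1)
  pa <- file.path(dir, "adj.tsv")
  write_adjacency(a, pa)
  a2 <- read_adjacency(pa, kind = "synthetic")
  expect_equal(a2$weights, a$weights, tolerance = 1e-12)
  # edge list form
  el <- data.frame(src = c("r1", "r2"), dst = c("r2", "r3"), w = c(1.5, 2))
  pe <- file.path(dir, "edges.tsv")
  write.table(el, pe, sep = "\t", row.names = FALSE, col.names = FALSE,
              quote = FALSE)
  ae <- read_adjacency(pe, regions = c("r1", "r2", "r3"))
  expect_equal(ae$weights["r1", "r2"], 1.5)
  expect_equal(ae$weights["r3", "r2"], 2)
  expect_equal(ae$weights, t(ae$weights))
})
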