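# Perturbation-based directed influence.

test_that("perturbation zeroes one region's past and nothing else", {
  set.seed(1)
  s <- list(past = matrix(rnorm(12, sd = 0.1), 3, 4),
            future = matrix(rnorm(6), 3, 2))
  p <- perturb_sample(s, 2)
  expect_equal(p$past[2, ], rep(0, 4))
  expect_identical(p$past[-2, ], s$past[-2, ])
  expect_identical(p$future, s$future)
  # silencing every region empties the window
  for (r in 1:3) s <- perturb_sample(s, r)
  expect_equal(s$past, matrix(0, 3, 4))
  # non-standardized input warns
  off <- list(past = matrix(5, 2, 3), future = matrix(0, 2, 1))
  expect_warning(perturb_sample(off, 1), "standardized")
})

test_that("a spatially decoupled model has zero off-diagonal influence", {
  fx <- tiny_benchmark(seed = 2, t_len = 160, n = 6)
  m <- dcrnn(fx$sp0, 3, 3, hidden = 4, layers = 1, seed = 3)
  im <- influence_matrix(m, fx$prep$splits$test)
  offdiag <- im$I[row(im$I) != col(im$I)]
  expect_equal(offdiag, rep(0, length(offdiag)))
  expect_true(all(diag(im$I) >= 0))
})

test_that("the analytic linear model matches its closed-form influence", {
  set.seed(4)
  n <- 6
  a <- make_graph(n, 0.4, seed = 5)
  tm <- transition_matrix(a)$T
  coef <- 0.5 * diag(n) + 0.4 * tm
  t_f <- 4
  model <- linear_model(coef, t_f)
  cfg <- synthetic_config(n = n, t_len = 120, sessions = 1, seed = 6)
  sess <- simulate_signals(a, cfg, seed = 6)
  prep <- prepare_data(list(sess), t_p = 3, t_f = t_f, scale_mode = "zscore")
  w <- prep$splits$test
  im <- influence_matrix(model, w)
  # closed form: zeroing region j changes the last state by e_j x_j, and the
  # s-step prediction by coef^s e_j x_j
  powers <- list(coef)
  for (s in 2:t_f) powers[[s]] <- coef %*% powers[[s - 1]]
  nw <- n_windows(w)
  expected <- matrix(0, n, n)
  for (i in seq_len(nw)) {
    xlast <- window_sample(w, i)$past[, 3]
    for (j in seq_len(n)) {
      diffs <- vapply(powers, function(pw) abs(pw[, j] * xlast[j]),
                      numeric(n))
      expected[, j] <- expected[, j] + rowSums(diffs)
    }
  }
  expected <- expected / (nw * t_f)
  expect_lt(max(abs(im$I - expected)), 1e-10)
  expect_true(all(im$I >= 0))
})

test_that("rescaling maps the off-diagonal range onto [0, 100]", {
  im <- structure(list(I = matrix(1:16, 4, 4) / 7, S = 3, t_f = 2,
                       targets = 1:4, rescaled = FALSE),
                  class = "influence_matrix")
  rs <- rescale_0_100(im)
  off <- rs$I[row(rs$I) != col(rs$I)]
  expect_equal(min(off), 0)
  expect_equal(max(off), 100)
  expect_true(all(is.na(diag(rs$I))))
  flat <- structure(list(I = matrix(1, 3, 3), S = 1, t_f = 1,
                         targets = 1:3, rescaled = FALSE),
                    class = "influence_matrix")
  expect_error(rescale_0_100(flat), "degenerate")
})

test_that("influence is equivariant under region relabeling", {
  set.seed(7)
  n <- 5
  a <- make_graph(n, 0.5, seed = 8)
  coef <- 0.5 * diag(n) + 0.4 * transition_matrix(a)$T
  cfg <- synthetic_config(n = n, t_len = 120, sessions = 1, seed = 9)
  sess <- simulate_signals(a, cfg, seed = 9)
  prep <- prepare_data(list(sess), t_p = 3, t_f = 3, scale_mode = "zscore")
  im <- influence_matrix(linear_model(coef, 3), prep$splits$test)
  perm <- c(3, 5, 1, 2, 4)
  # permute data, graph and model consistently
  sess_p <- session_ts(sess$values[perm, ], sess$sampling_interval, "perm")
  prep_p <- prepare_data(list(sess_p), t_p = 3, t_f = 3,
                         scale_mode = "zscore")
  im_p <- influence_matrix(linear_model(coef[perm, perm], 3),
                           prep_p$splits$test)
  expect_equal(im_p$I, im$I[perm, perm], tolerance = 1e-10)
})

test_that("influence respects the graph's hop structure on a path", {
  # untrained 1-layer DCGRU with K = 1, one encoder and one decoder step.
  # Hop budget: the encoder step reaches 1 hop; in the decoder step the
  # reset gate (2 hops) modulates the hidden state before the candidate's
  # graph convolution, so information travels at most 3 hops in total.
  g <- path_graph(6)
  sp <- spatial_spec("operator", operator = transition_matrix(g), k = 1)
  m <- dcrnn(sp, t_p = 1, t_f = 1, hidden = 4, layers = 1, seed = 10)
  x <- matrix(rnorm(6), 6, 1)
  base <- forecast(m, x)
  xp <- x; xp[6, ] <- 0
  d <- abs(forecast(m, xp) - base)
  expect_equal(d[1:2], rep(0, 2))   # nodes 1-2 are > 3 hops from node 6
  expect_gt(max(d[4:6]), 0)
})

test_that("edge-recovery AUC is 1 for an influence matrix aligned with edges", {
  a <- make_graph(8, 0.3, seed = 11)
  im <- structure(list(I = (a$weights > 0) * 1 +
                         matrix(runif(64, 0, 0.01), 8, 8),
                       S = 1, t_f = 1, targets = 1:8, rescaled = FALSE),
                  class = "influence_matrix")
  expect_gt(influence_edge_auc(im, a), 0.99)
})
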