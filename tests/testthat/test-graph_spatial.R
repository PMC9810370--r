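# Transition operators and graph convolutions against dense oracles.

test_that("transition operator row-normalizes and handles degenerate rows", {
  tm <- transition_matrix(matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(tm$T, matrix(c(0, 1, 1, 0), 2, 2))
  tm3 <- transition_matrix(path_graph3())
  expect_equal(tm3$T[2, ], c(0.5, 0, 0.5))
  pos <- tm3$degree > 0
  expect_equal(rowSums(tm3$T)[pos], rep(1, sum(pos)))
  # zero-degree node keeps an all-zero row
  a <- matrix(0, 3, 3); a[1, 2] <- a[2, 1] <- 1
  tz <- transition_matrix(a)
  expect_equal(tz$T[3, ], rep(0, 3))
  # invariance under global weight rescaling
  set.seed(1)
  w <- matrix(runif(16), 4, 4); w <- w + t(w); diag(w) <- 0
  expect_equal(transition_matrix(w)$T, transition_matrix(7.3 * w)$T)
  # negative weights: clipped by default, error on request
  neg <- matrix(c(0, -1, -1, 0), 2, 2)
  expect_equal(transition_matrix(neg)$T, matrix(0, 2, 2))
  expect_equal(transition_matrix(neg, "absolute")$T,
               matrix(c(0, 1, 1, 0), 2, 2))
  expect_error(transition_matrix(neg, "error"), "negative")
})

test_that("diffusion convolution reduces to identity and matches hand cases", {
  tm <- transition_matrix(path_graph3())
  f_id <- diffusion_filter(array(1, c(1, 1, 1)))
  x <- matrix(c(1, 0, 0), 3, 1)
  expect_equal(diffusion_convolution(x, tm, f_id), x)
  f_t <- diffusion_filter(array(c(0, 1), c(2, 1, 1)))
  expect_equal(diffusion_convolution(x, tm, f_t),
               matrix(c(0, 0.5, 0), 3, 1))
})

test_that("diffusion and hybrid convolutions match the dense power-series oracle", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(2:20, 1)
    k <- sample(0:4, 1)
    m_in <- sample(1:3, 1); q <- sample(1:3, 1)
    a <- make_graph(n, runif(1, 0.1, 0.9), seed = i)
    tm <- transition_matrix(a)
    theta <- array(rnorm((k + 1) * q * m_in), c(k + 1, q, m_in))
    x <- matrix(rnorm(n * m_in), n, m_in)
    flt <- diffusion_filter(theta)
    expect_lt(max(abs(diffusion_convolution(x, tm, flt) -
                        dense_diffusion_oracle(x, tm$T, theta))), 1e-10)
    # hybrid: diffusion branch + adaptive branch vs summed oracles
    v <- matrix(rnorm(n * n), n, n)
    aa <- adaptive_adjacency(v)
    theta2 <- array(rnorm((k + 1) * q * m_in), c(k + 1, q, m_in))
    hyb <- graph_conv_hybrid(x, tm, aa, flt, diffusion_filter(theta2))
    expect_lt(max(abs(hyb - (dense_diffusion_oracle(x, tm$T, theta) +
                               dense_diffusion_oracle(x, aa, theta2)))),
              1e-10)
  }
})

test_that("hybrid convolution reduces to its single-operator variants", {
  set.seed(11)
  n <- 8; k <- 2
  a <- make_graph(n, 0.4, seed = 3)
  tm <- transition_matrix(a)
  theta <- array(rnorm((k + 1) * 2), c(k + 1, 2, 1))
  x <- matrix(rnorm(n), n, 1)
  flt <- diffusion_filter(theta)
  zero_flt <- diffusion_filter(array(0, c(k + 1, 2, 1)))
  aa <- adaptive_adjacency(matrix(rnorm(n * n), n, n))
  expect_equal(graph_conv_hybrid(x, tm, aa, flt, zero_flt),
               diffusion_convolution(x, tm, flt))
  expect_equal(graph_conv_hybrid(x, NULL, aa, filter_adap = flt),
               dense_diffusion_oracle(x, aa, theta))
  expect_equal(graph_conv_hybrid(x, tm, aa, zero_flt, zero_flt),
               matrix(0, n, 2))
  expect_error(graph_conv_hybrid(x), "at least one")
})

test_that("adaptive adjacency is tanh(V)/N with entries inside (-1/N, 1/N)", {
  expect_equal(adaptive_adjacency(matrix(0, 3, 3)), matrix(0, 3, 3))
  v <- matrix(1, 4, 4)
  expect_equal(adaptive_adjacency(v)[1, 1], tanh(1) / 4)
  expect_equal(round(adaptive_adjacency(v)[1, 1], 6), 0.190399)
  set.seed(2)
  big <- adaptive_adjacency(matrix(rnorm(25, sd = 3), 5, 5))
  expect_true(all(abs(big) < 1 / 5))
  # saturation never escapes the closed bound
  sat <- adaptive_adjacency(matrix(1e6, 5, 5))
  expect_true(all(abs(sat) <= 1 / 5))
  expect_error(adaptive_adjacency(matrix(0, 2, 3)), "square")
})

test_that("no information crosses disconnected components for any K", {
  # two disjoint path components: 1-2-3 and 4-5
  a <- matrix(0, 5, 5)
  a[1, 2] <- a[2, 1] <- a[2, 3] <- a[3, 2] <- a[4, 5] <- a[5, 4] <- 1
  tm <- transition_matrix(a)
  set.seed(4)
  for (k in 0:4) {
    theta <- array(rnorm(k + 1), c(k + 1, 1, 1))
    flt <- diffusion_filter(theta)
    x <- matrix(rnorm(5), 5, 1)
    base <- diffusion_convolution(x, tm, flt)
    x2 <- x; x2[4] <- x2[4] + 10   # perturb the other component
    pert <- diffusion_convolution(x2, tm, flt)
    expect_equal(pert[1:3, ], base[1:3, ])
  }
})

test_that("adjacency constructor enforces symmetry and finiteness", {
  expect_error(weighted_adjacency(matrix(c(0, 1, 0, 0), 2, 2), "SC"),
               "symmetric")
  expect_error(weighted_adjacency(matrix(c(0, Inf, Inf, 0), 2, 2), "SC"),
               "finite")
  expect_silent(weighted_adjacency(matrix(c(0, -0.2, 0.3, 0), 2, 2), "CE"))
})
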