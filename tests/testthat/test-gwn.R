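# Dilated causal convolutions, gated TCN units and the graph WaveNet.

test_that("dilated causal convolution matches hand cases and a naive loop", {
  # R = 1: pointwise channel mixing only
  x <- matrix(1:6, 2, 3)
  th1 <- array(c(2, 0, 0, 3), c(1, 2, 2))
  expect_equal(dilated_causal_conv(x, th1, d = 1),
               matrix(th1[1, , ], 2, 2) %*% x)
  # d = 1, R = 2, scalar kernel (1, 1): y = x_t + x_{t-1}
  expect_equal(dilated_causal_conv(matrix(c(1, 2, 3), 1), c(1, 1), d = 1),
               matrix(c(1, 3, 5), 1))
  # naive O(T R) loop oracle on random instances
  set.seed(5)
  for (i in 1:20) {
    cin <- sample(1:3, 1); cout <- sample(1:3, 1)
    r_w <- sample(1:3, 1); d <- sample(1:3, 1); tt <- sample(5:15, 1)
    xs <- matrix(rnorm(cin * tt), cin, tt)
    th <- array(rnorm(r_w * cout * cin), c(r_w, cout, cin))
    naive <- matrix(0, cout, tt)
    for (t in seq_len(tt)) for (r in 0:(r_w - 1)) {
      src <- t - d * r
      if (src >= 1)
        naive[, t] <- naive[, t] + matrix(th[r + 1, , ], cout, cin) %*% xs[, src]
    }
    expect_lt(max(abs(dilated_causal_conv(xs, th, d) - naive)), 1e-12)
  }
  expect_error(dilated_causal_conv(x, th1, d = 0), "dilation")
})

test_that("perturbing the future never changes past outputs", {
  set.seed(6)
  xs <- matrix(rnorm(2 * 12), 2, 12)
  th <- array(rnorm(2 * 2 * 2), c(2, 2, 2))
  base <- dilated_causal_conv(xs, th, d = 2)
  for (t in 5:12) {
    xp <- xs; xp[, t] <- xp[, t] + 10
    pert <- dilated_causal_conv(xp, th, d = 2)
    if (t > 1)
      expect_equal(pert[, 1:(t - 1)], base[, 1:(t - 1)])
  }
})

test_that("gated TCN multiplies a tanh filter with a logistic gate", {
  set.seed(7)
  xs <- matrix(rnorm(2 * 8), 2, 8)
  params <- list(theta1 = array(0, c(2, 2, 2)), b1 = 0,
                 theta2 = array(rnorm(8), c(2, 2, 2)), b2 = 0)
  expect_equal(gated_tcn(xs, params), matrix(0, 2, 8))
  params$theta1 <- array(rnorm(8), c(2, 2, 2))
  out <- gated_tcn(xs, params)
  expect_true(all(abs(out) < 1))
  # gate bias -> -infinity limit kills the output
  params$b2 <- -1e4
  expect_lt(max(abs(gated_tcn(xs, params))), 1e-12)
})

test_that("the default configuration stacks 24 gated layers", {
  sp <- spatial_spec("none", n_nodes = 4)
  m <- gwn(sp, t_p = 60, t_f = 60, seed = 1)
  expect_length(m$layers, 24L)
  expect_equal(m$dilations, rep(c(1, 2), 12))
  expect_equal(gwn_receptive_field(m), 1 + 1 * sum(rep(c(1, 2), 12)))
})

test_that("the empirical receptive field equals the closed form", {
  sp <- spatial_spec("none", n_nodes = 2)
  m <- gwn(sp, t_p = 10, t_f = 2, channels = 4, blocks = 2,
           layers_per_block = 2, seed = 3)
  rf <- gwn_receptive_field(m)          # 1 + (1+2+1+2) = 7
  expect_equal(rf, 7L)
  gb <- asNamespace("graphbold")
  # probe causality of the temporal stack before the dense head: the last
  # time step of the skip representation must react to inputs within the
  # receptive field and ignore older ones
  stack_last <- function(past) {
    steps <- gb$gb_stack_batch(gb$gb_as_batch_array(past))
    states <- lapply(steps, function(x)
      gb$gb_add(gb$gb_matmul(gb$gb_const(x), m$w_in), m$b_in))
    skip <- NULL
    for (layer in m$layers) {
      filt <- gb$gb_dcc_apply(states, layer$filt_w, layer$filt_b, layer$d)
      gate <- gb$gb_dcc_apply(states, layer$gate_w, layer$gate_b, layer$d)
      gated <- lapply(seq_along(states), function(t)
        gb$gb_mul(gb$gb_tanh(filt[[t]]), gb$gb_sigmoid(gate[[t]])))
      gc_out <- lapply(gated, function(x)
        gb$gb_relu(gb$gb_gconv_apply(x, layer$gconv, m$spatial, m$v)))
      skip <- if (is.null(skip)) gc_out
              else lapply(seq_along(states), function(t)
                gb$gb_add(skip[[t]], gc_out[[t]]))
      states <- lapply(seq_along(states), function(t)
        gb$gb_add(states[[t]], gc_out[[t]]))
    }
    skip[[length(skip)]]$val
  }
  set.seed(4)
  past <- matrix(rnorm(20), 2, 10)
  base <- stack_last(past)
  reacts <- logical(10)
  for (t in 1:10) {
    pp <- past; pp[, t] <- pp[, t] + 5
    reacts[t] <- max(abs(stack_last(pp) - base)) > 1e-9
  }
  expect_equal(which(reacts), (10 - rf + 1):10)
})

test_that("gwn forecasts have the contracted shape and a zero model is flat", {
  a <- make_graph(5, 0.5, seed = 2)
  sp <- spatial_spec("operator", operator = transition_matrix(a), k = 2)
  m <- gwn(sp, t_p = 8, t_f = 6, channels = 4, blocks = 1,
           layers_per_block = 2, seed = 2)
  out <- forecast(m, matrix(rnorm(40), 5, 8))
  expect_equal(dim(out), c(5L, 6L))
  outb <- forecast(m, array(rnorm(5 * 8 * 3), c(5, 8, 3)))
  expect_equal(dim(outb), c(5L, 6L, 3L))
  mz <- zero_model(gwn(sp, t_p = 8, t_f = 6, channels = 4, blocks = 1,
                       layers_per_block = 2))
  expect_equal(forecast(mz, matrix(rnorm(40), 5, 8)), matrix(0, 5, 6))
})

test_that("gwn with K = 0 is equivariant under region permutation", {
  sp <- spatial_spec("none", n_nodes = 6)
  m <- gwn(sp, t_p = 6, t_f = 4, channels = 4, blocks = 1,
           layers_per_block = 2, seed = 5)
  past <- matrix(rnorm(36), 6, 6)
  perm <- sample(6)
  expect_equal(forecast(m, past[perm, ]), forecast(m, past)[perm, ],
               tolerance = 1e-12)
})
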