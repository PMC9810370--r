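# Shared fixtures: small graphs, sessions and window sets built in code.

# 3-node path graph 1 - 2 - 3 with unit weights
path_graph3 <- function() {
  a <- matrix(0, 3, 3)
  a[1, 2] <- a[2, 1] <- 1
  a[2, 3] <- a[3, 2] <- 1
  weighted_adjacency(a, "synthetic")
}

# path graph on n nodes
path_graph <- function(n) {
  a <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) a[i, i + 1L] <- a[i + 1L, i] <- 1
  weighted_adjacency(a, "synthetic")
}

random_session <- function(n = 4, t = 50, seed = 1, dt = 0.72) {
  set.seed(seed)
  session_ts(matrix(rnorm(n * t), n, t), dt, sprintf("rnd_%d", seed))
}

# tiny prepared benchmark for training-based tests
tiny_benchmark <- function(seed = 1, t_len = 300, t_p = 3, t_f = 3, n = 10) {
  cfg <- synthetic_config(n = n, t_len = t_len, sessions = 1, seed = seed)
  bench <- make_benchmark(cfg)
  prep <- prepare_data(bench$sessions, t_p = t_p, t_f = t_f)
  list(bench = bench, prep = prep,
       sp1 = spatial_spec("operator", operator = bench$operator, k = 1),
       sp0 = spatial_spec("none", n_nodes = n))
}

# set every parameter of a model to zero
zero_model <- function(model) {
  for (p in graphbold:::gb_collect_params(model)) p$val[] <- 0
  model
}

# dense power-series oracle: sum_k x %*% t(theta[k+1,,]) after T^k
dense_diffusion_oracle <- function(x, tm, theta, activation = identity) {
  kmax <- dim(theta)[1L] - 1L
  q <- dim(theta)[2L]
  out <- matrix(0, nrow(x), q)
  for (k in 0:kmax) {
    tk <- diag(nrow(tm))
    for (i in seq_len(k)) tk <- tk %*% tm
    out <- out + (tk %*% x) %*% t(matrix(theta[k + 1L, , ], q, ncol(x)))
  }
  activation(out)
}
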