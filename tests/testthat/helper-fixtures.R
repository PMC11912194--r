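# shared fixtures: random stochastic matrices and toy-model shortcuts

random_stochastic <- function(n, seed) {
  withr::with_seed(seed, {
    M <- matrix(stats::runif(n * n, min = 0.05, max = 1), n, n)
  })
  stochastic_matrix(sweep(M, 2, colSums(M), "/"))
}

toy_fixture <- function(h, k) {
  p <- toy_params(h, k)
  list(p = p, tmat = toy_micro_matrix(p), agg = toy_macro_aggregation(p))
}

# brute-force slowest timescale straight from base eigen(), independent of
# the package's implied_timescales()
oracle_slowest <- function(M, lag = 1) {
  vals <- Mod(eigen(M, only.values = TRUE)$values)
  vals <- sort(vals, decreasing = TRUE)[-1]
  -lag / log(vals[1])
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), tol)
}
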