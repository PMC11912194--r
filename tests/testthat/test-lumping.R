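test_that("aggregation construction derives populations and rejects bad maps", {
  fix <- toy_fixture(0.3, 0.1)
  expect_equal(unname(fix$agg$macro_Pi), c(0.5, 0.5))
  expect_equal(colSums(fix$agg$A_hat), c(0.5, 0.5) / 0.5 * 1, ignore_attr = TRUE)
  expect_equal(colSums(fix$agg$A_hat), c(1, 1), ignore_attr = TRUE)
  expect_equal(rowSums(fix$agg$A), rep(1, 4))
  # t(A) %*% A_hat is the identity
  expect_matrix_equal(t(fix$agg$A) %*% fix$agg$A_hat, diag(2), tol = 1e-14)
  # identity lumping needs n macrostates
  T6 <- random_stochastic(4, 5)
  agg_id <- build_aggregation(T6, 1:4)
  expect_matrix_equal(agg_id$A, diag(4), tol = 1e-15)
  expect_matrix_equal(agg_id$A_hat, diag(4), tol = 1e-14)
  expect_error(build_aggregation(fix$tmat, c(1, 1, 2)), "covers 3 microstates")
  expect_error(build_aggregation(fix$tmat, c(1, 1, 1, 1)), "at least 2")
  # two-column table input, 0-based microstates
  tab <- data.frame(micro = 0:3, macro = c("L", "L", "R", "R"))
  agg_tab <- build_aggregation(fix$tmat, tab)
  expect_equal(agg_tab$assignment, fix$agg$assignment)
})

test_that("population projection sums microstates into macrostates", {
  fix <- toy_fixture(0.2, 0.2)
  expect_equal(unname(project_populations(fix$agg, fix$agg$micro_pi)),
               unname(fix$agg$macro_Pi))
  expect_equal(unname(project_populations(fix$agg, c(1, 0, 0, 0))), c(1, 0))
  expect_equal(unname(project_populations(fix$agg, c(0.5, 0.5, 0, 0))), c(1, 0))
  expect_error(project_populations(fix$agg, c(1, 0)), "DimensionMismatch")
})

test_that("local-equilibrium projection matches flux counting and the toy closed form", {
  # off-diagonal h/2, independent of k
  for (k in c(0.1, 0.3)) {
    fix <- toy_fixture(0.5, k)
    TLE <- lump_LE(fix$agg, fix$tmat)
    expect_equal(as.matrix(TLE)[2, 1], 0.25, tolerance = 1e-12)
    expect_equal(slowest_timescale(TLE), -1 / log(1 - 0.5), tolerance = 1e-12)
  }
  # identity lumping returns the microstate matrix
  T5 <- random_stochastic(5, 8)
  expect_matrix_equal(lump_LE(build_aggregation(T5, 1:5), T5), T5, tol = 1e-12)
})

test_that("flux identity pins the projection: T[I,J] Pi[J] = sum of t[i,j] pi[j]", {
  for (seed in 1:4) {
    T <- random_stochastic(6, 20 + seed)
    assign <- c(1, 1, 2, 2, 3, 3)
    agg <- build_aggregation(T, assign)
    TLE <- lump_LE(agg, T)
    pi <- agg$micro_pi
    for (I in 1:3) for (J in 1:3) {
      flux <- sum(outer(assign == I, assign == J) * as.matrix(T) *
                    rep(pi, each = 6))
      expect_equal(as.matrix(TLE)[I, J] * agg$macro_Pi[[J]], flux,
                   tolerance = 1e-12)
    }
  }
})

test_that("all three estimators preserve the macrostate equilibrium", {
  for (seed in 1:3) {
    T <- random_stochastic(6, 40 + seed)
    agg <- build_aggregation(T, c(1, 2, 2, 3, 3, 3))
    Pi <- agg$macro_Pi
    for (M in list(lump_LE(agg, T), lump_HS(agg, T), lump_Mic(agg, T, 5))) {
      expect_lt(max(abs(as.matrix(M) %*% Pi - Pi)), 1e-10)
    }
  }
})

test_that("microstate-based projection equals LE at one step and is exact on populations", {
  fix <- toy_fixture(0.5, 0.1)
  expect_matrix_equal(lump_Mic(fix$agg, fix$tmat, 1), lump_LE(fix$agg, fix$tmat),
                      tol = 1e-14)
  # survival of macrostate L after one step from within-L equilibrium
  expect_equal(as.matrix(lump_Mic(fix$agg, fix$tmat, 1))[1, 1], 0.75,
               tolerance = 1e-14)
  # exact macrostate populations for within-state-equilibrated starts
  P0 <- c(1, 0)
  p0 <- drop(fix$agg$A_hat %*% P0)
  for (m in c(1, 2, 7, 33, 100, 1000)) {
    Tm <- as.matrix(propagate_power(fix$tmat, m))
    direct <- drop(t(fix$agg$A) %*% Tm %*% p0)
    viaT <- drop(as.matrix(lump_Mic(fix$agg, fix$tmat, m)) %*% P0)
    expect_equal(viaT, direct, tolerance = 1e-12, ignore_attr = TRUE)
  }
  # time dependence: T_Mic(2 tau) differs from T_Mic(tau)^2 when lumping is bad
  M1 <- as.matrix(lump_Mic(fix$agg, fix$tmat, 1))
  M2 <- as.matrix(lump_Mic(fix$agg, fix$tmat, 2))
  expect_gt(max(abs(M2 - M1 %*% M1)), 1e-3)
})

test_that("Hummer-Szabo projection is exact under identity lumping and on the toy model", {
  T5 <- random_stochastic(5, 77)
  expect_matrix_equal(lump_HS(build_aggregation(T5, 1:5), T5), T5, tol = 1e-10)
  # weakly non-Markovian four-well model: timescale 13% below the reference
  fix <- toy_fixture(0.1, 0.1)
  deficit <- 100 * (1 - slowest_timescale(lump_HS(fix$agg, fix$tmat)) /
                      slowest_timescale(fix$tmat))
  expect_equal(deficit, 12.506, tolerance = 1e-3)
  # closed form hk/(h+2k) for the off-diagonal across a parameter grid
  for (hk in list(c(0.1, 0.1), c(0.5, 0.1), c(0.1, 0.5), c(0.25, 0.2))) {
    fx <- toy_fixture(hk[1], hk[2])
    a <- hk[1] * hk[2] / (hk[1] + 2 * hk[2])
    expect_equal(as.matrix(lump_HS(fx$agg, fx$tmat))[2, 1], a,
                 tolerance = 1e-12)
  }
})

test_that("projected series is the identity at zero and matches lump_Mic", {
  fix <- toy_fixture(0.2, 0.1)
  ser <- project_series(fix$agg, fix$tmat, 5)
  expect_equal(as.matrix(ser[[1]]), diag(2), ignore_attr = TRUE)
  expect_matrix_equal(ser[[4]], lump_Mic(fix$agg, fix$tmat, 3), tol = 1e-13)
  expect_equal(vapply(ser, function(x) x$lag, 0), 0:5)
})

test_that("all estimators approach the microstate timescale when lumping is good", {
  # strong timescale separation h/k <= 1/30: LE, HS and long-time Mic
  # within 2% of the reference
  for (hk in list(c(0.01, 0.3), c(0.005, 0.15))) {
    fx <- toy_fixture(hk[1], hk[2])
    t_micro <- slowest_timescale(fx$tmat)
    r_le <- slowest_timescale(lump_LE(fx$agg, fx$tmat)) / t_micro
    r_hs <- slowest_timescale(lump_HS(fx$agg, fx$tmat)) / t_micro
    r_mic <- slowest_timescale(lump_Mic(fx$agg, fx$tmat, 1024)) / t_micro
    expect_lt(abs(r_le - 1), 0.02)
    expect_lt(abs(r_hs - 1), 0.02)
    expect_lt(abs(r_mic - 1), 0.02)
  }
})
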