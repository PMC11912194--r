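test_that("trajectory files parse, re-index densely and reject bad input", {
  f <- withr::local_tempfile()
  writeLines(c("0", "0", "1"), f)
  ts <- read_trajectories(f, dt = 1)
  expect_equal(ts$trajectories[[1]]$labels, c(0L, 0L, 1L))
  # sparse original alphabet becomes dense with a retained map
  f2 <- withr::local_tempfile()
  writeLines(c("3", "7", "3", "7"), f2)
  ts2 <- read_trajectories(f2)
  expect_equal(ts2$trajectories[[1]]$labels, c(0L, 1L, 0L, 1L))
  expect_equal(ts2$state_map, c("3" = 0L, "7" = 1L))
  f3 <- withr::local_tempfile()
  writeLines(c("0", "x", "1"), f3)
  expect_error(read_trajectories(f3), "ParseError")
  f4 <- withr::local_tempfile()
  writeLines(character(), f4)
  expect_error(read_trajectories(f4), "EmptyFile")
  # gz round trip and CSV column selection
  fgz <- withr::local_tempfile(fileext = ".gz")
  write_trajectory(discrete_trajectory(c(1L, 0L, 1L)), fgz)
  expect_equal(read_trajectories(fgz)$trajectories[[1]]$labels, c(1L, 0L, 1L))
  fcsv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(frame = 1:3, state = c(2L, 2L, 5L)), fcsv,
                   row.names = FALSE)
  expect_equal(read_trajectories(fcsv, column = "state")$trajectories[[1]]$labels,
               c(0L, 0L, 1L))
})

test_that("transition counting matches hand counts and boundary rules", {
  tr <- trajectory_set(discrete_trajectory(c(0, 0, 1, 1, 0)))
  C <- count_transitions(tr, 1)
  expect_equal(C$counts, matrix(c(1, 1, 1, 1), 2))  # col = origin state
  C2 <- count_transitions(trajectory_set(discrete_trajectory(c(0, 1, 0, 1))), 2)
  expect_equal(C2$counts, matrix(c(1, 0, 0, 1), 2))
  # pairs never cross trajectory boundaries
  two <- trajectory_set(list(discrete_trajectory(c(0, 1)),
                             discrete_trajectory(c(1, 0))))
  C3 <- count_transitions(two, 1)
  expect_equal(C3$counts, matrix(c(0, 1, 1, 0), 2))
  expect_error(count_transitions(two, 2), "LagTooLong")
  expect_error(count_transitions(two, 0.5), "multiple of dt")
})

test_that("sliding and strided counting totals obey the frame arithmetic", {
  withr::with_seed(7, {
    lens <- c(53, 97, 200)
    trs <- lapply(lens, function(n)
      discrete_trajectory(sample(0:2, n, replace = TRUE)))
  })
  ts <- trajectory_set(trs)
  for (lagf in c(1, 3, 7)) {
    expect_equal(sum(count_transitions(ts, lagf, "sliding")$counts),
                 sum(lens - lagf))
    origins <- sum(vapply(lens, function(n) length(seq(1, n - lagf, by = lagf)), 0))
    expect_equal(sum(count_transitions(ts, lagf, "strided")$counts), origins)
  }
})

test_that("transition-matrix estimation normalizes, symmetrizes and trims", {
  C <- structure(list(counts = matrix(c(1, 1, 1, 1), 2), lag = 1,
                      mode = "sliding"), class = "count_matrix")
  expect_equal(as.matrix(estimate_transition_matrix(C)),
               matrix(0.5, 2, 2))
  C2 <- structure(list(counts = matrix(c(8, 2, 1, 9), 2), lag = 1,
                       mode = "sliding"), class = "count_matrix")
  expect_equal(as.matrix(estimate_transition_matrix(C2)),
               matrix(c(0.8, 0.2, 0.1, 0.9), 2))
  # symmetrized counts: (C + t(C)) / 2 = [[8, 1.5], [1.5, 9]]
  sym <- as.matrix(estimate_transition_matrix(C2, symmetrize = TRUE))
  expect_equal(sym, matrix(c(8 / 9.5, 1.5 / 9.5, 1.5 / 10.5, 9 / 10.5), 2))
  # state 2 only feeds into state 0 and is never re-entered: trimmed
  C3 <- structure(list(counts = matrix(c(5, 5, 0,
                                         5, 5, 0,
                                         3, 0, 0), 3), lag = 1,
                       mode = "sliding"), class = "count_matrix")
  expect_warning(T3 <- estimate_transition_matrix(C3), "dropping 1 state")
  expect_equal(attr(T3, "dropped_states"), 2L)
  expect_equal(dim(as.matrix(T3)), c(2L, 2L))
  bad <- structure(list(counts = matrix(c(0, 1, 0, 0), 2), lag = 1,
                        mode = "sliding"), class = "count_matrix")
  expect_error(suppressWarnings(estimate_transition_matrix(bad)),
               "AllDisconnected")
})

test_that("count estimator is consistent on long sampled chains", {
  fix <- toy_fixture(0.1, 0.1)
  traj <- sample_chain(fix$tmat, 1e6, seed = 2024)
  est <- estimate_transition_matrix(count_transitions(trajectory_set(traj), 1))
  expect_lt(max(abs(as.matrix(est) - as.matrix(fix$tmat))), 0.01)
})

test_that("directly counted series starts at identity and obeys CK on Markov data", {
  fix <- toy_fixture(0.1, 0.1)
  traj <- sample_chain(fix$tmat, 2e5, seed = 9)
  ts <- trajectory_set(traj)
  series <- transition_matrix_series(ts, c(0, 1, 2))
  expect_equal(as.matrix(series[[1]]), diag(4))
  expect_equal(series[[1]]$lag, 0)
  # T_MD(2) ~ T_MD(1)^2 within sampling error for a Markov chain
  expect_lt(max(abs(as.matrix(series[[3]]) -
                    as.matrix(series[[2]]) %*% as.matrix(series[[2]]))), 0.02)
  # T_MD(1) ~ truth
  expect_lt(max(abs(as.matrix(series[[2]]) - as.matrix(fix$tmat))), 0.02)
  short <- trajectory_set(discrete_trajectory(rep(c(0, 1), 30)))
  expect_error(transition_matrix_series(short, c(0, 1), min_origins = 100),
               "InsufficientOrigins")
})

test_that("splitting preserves frames, drops remainders and reports edge cases", {
  tr <- trajectory_set(discrete_trajectory(0:9))
  expect_message(sp <- split_trajectories(tr, 3), "dropped 1")
  expect_length(sp$trajectories, 3)
  expect_equal(attr(sp, "dropped_frames"), 1L)
  expect_equal(unlist(lapply(sp$trajectories, function(t) t$labels)), 0:8)
  # the large-scale splitting regime: 150-frame pieces of a 1.5e6-frame run
  big <- trajectory_set(discrete_trajectory(rep_len(c(0L, 1L), 1.5e6)))
  sp_big <- split_trajectories(big, 150)
  expect_length(sp_big$trajectories, 10000)
  expect_equal(attr(sp_big, "dropped_frames"), 0L)
  # segment equal to the trajectory: unchanged; longer: empty plus report
  same <- split_trajectories(trajectory_set(discrete_trajectory(0:4)), 5)
  expect_length(same$trajectories, 1)
  expect_equal(same$trajectories[[1]]$labels, 0:4)
  expect_message(none <- split_trajectories(
    trajectory_set(discrete_trajectory(0:4)), 9), "no segment fits")
  expect_length(none$trajectories, 0)
  expect_equal(attr(none, "dropped_frames"), 5L)
})

test_that("estimates from many short segments agree with the full-trajectory estimate", {
  fix <- toy_fixture(0.1, 0.1)
  traj <- sample_chain(fix$tmat, 3e5, seed = 31)
  full <- estimate_transition_matrix(count_transitions(trajectory_set(traj), 1))
  segs <- split_trajectories(trajectory_set(traj), 150)
  short <- estimate_transition_matrix(count_transitions(segs, 1))
  expect_lt(max(abs(as.matrix(full) - as.matrix(short))), 0.01)
  # and both are near the truth
  expect_lt(max(abs(as.matrix(short) - as.matrix(fix$tmat))), 0.02)
})
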