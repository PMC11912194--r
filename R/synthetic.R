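#' Parameters of the four-well toy model
#'
#' A one-dimensional landscape with four microstates, lumped pairwise into
#' two macrostates L = \{1, 2\} and R = \{3, 4\}. `k` is the intrastate
#' hopping probability per step (1-2 and 3-4), `h` the interstate one
#' (2-3). Their ratio `h/k` is the Markovianity parameter of the lumped
#' model: `h/k << 1` separates timescales (good lumping), `h/k >= 1` does
#' not. The constraint `h + k <= 1` keeps every entry of the microstate
#' matrix (`1 - k`, `1 - h - k`, `h`, `k`) in `[0, 1]`.
#'
#' @param h Interstate transition probability per step, > 0.
#' @param k Intrastate transition probability per step, > 0.
#' @param tau0 Unit time of one step (default 1), making timescales
#'   dimensionless multiples of `tau0`.
#' @return Object of class `toy_params`.
#' @export
toy_params <- function(h, k, tau0 = 1) {
  if (!is.numeric(h) || !is.numeric(k) || h <= 0 || k <= 0 || h + k > 1) {
    stop("InvalidParams: need h > 0, k > 0, h + k <= 1", call. = FALSE)
  }
  if (tau0 <= 0) stop("InvalidParams: tau0 must be positive", call. = FALSE)
  structure(list(h = h, k = k, tau0 = tau0), class = "toy_params")
}

#' @export
print.toy_params <- function(x, ...) {
  cat(sprintf("toy_params: h = %g, k = %g (h/k = %g), tau0 = %g\n",
              x$h, x$k, x$h / x$k, x$tau0))
  invisible(x)
}

#' Microstate transition matrix of the toy model
#'
#' The symmetric tridiagonal 4 x 4 matrix coupling 1-2 and 3-4 with `k`
#' and 2-3 with `h`, diagonal filled so each column sums to one. Symmetry
#' implies detailed balance with uniform equilibrium populations
#' `pi = 1/4`. Its eigenvalues are `1`, `1 - h - k +/- sqrt(h^2 + k^2)`
#' and `1 - 2k`.
#'
#' @param p A [toy_params()].
#' @return A 4-state [stochastic_matrix()] with lag `tau0`.
#' @examples
#' toy_micro_matrix(toy_params(0.1, 0.1))
#' @export
toy_micro_matrix <- function(p) {
  stopifnot(inherits(p, "toy_params"))
  h <- p$h; k <- p$k
  M <- matrix(c(
    1 - k, k,         0,         0,
    k,     1 - h - k, h,         0,
    0,     h,         1 - h - k, k,
    0,     0,         k,         1 - k), 4, 4, byrow = TRUE)
  stochastic_matrix(M, lag = p$tau0, labels = as.character(1:4))
}

#' Pairwise lumping of the toy model into L and R
#'
#' Microstates 1, 2 form macrostate L and 3, 4 form R, with equilibrium
#' macrostate populations `Pi = (1/2, 1/2)` and uniform within-state
#' equilibria.
#'
#' @param p A [toy_params()].
#' @return An [build_aggregation()] result over [toy_micro_matrix()].
#' @export
toy_macro_aggregation <- function(p) {
  build_aggregation(toy_micro_matrix(p), c("L", "L", "R", "R"))
}

#' Closed-form implied timescales of the toy model
#'
#' In units of `tau0`:
#' * `t_micro = -1 / log(1 - h - k + sqrt(h^2 + k^2))`, the slowest
#'   microstate relaxation (the reference);
#' * `t_LE = -1 / log(1 - h)`, the local-equilibrium macrostate timescale,
#'   independent of `k`;
#' * `t_HS = -1 / log(1 - 2 h k / (h + 2 k))`, the Hummer-Szabo macrostate
#'   timescale (off-diagonal element of the projected matrix is
#'   `h k / (h + 2 k)`).
#' All three agree with the corresponding numerical estimators to machine
#' precision.
#'
#' @param p A [toy_params()].
#' @return Named list with `t_micro`, `t_LE`, `t_HS`.
#' @examples
#' toy_analytic_timescales(toy_params(0.1, 0.5))
#' @export
toy_analytic_timescales <- function(p) {
  stopifnot(inherits(p, "toy_params"))
  h <- p$h; k <- p$k
  lam1 <- 1 - h - k + sqrt(h^2 + k^2)
  list(t_micro = -p$tau0 / log(lam1),
       t_LE = -p$tau0 / log(1 - h),
       t_HS = -p$tau0 / log(1 - 2 * h * k / (h + 2 * k)))
}

#' Sample a Markov chain from a transition matrix
#'
#' Seeded, reproducible Monte Carlo realization of the chain defined by a
#' column-stochastic matrix. The seed is scoped (the caller's RNG state is
#' untouched).
#'
#' @param T A [stochastic_matrix()].
#' @param length Number of frames, >= 2.
#' @param start Initial state: 0-based integer index, or `"stationary"` to
#'   draw from [stationary_distribution()].
#' @param seed Integer seed (required; no global random state is used).
#' @return A [discrete_trajectory()] with `dt` equal to the lag of `T`.
#' @export
sample_chain <- function(T, length, start = "stationary", seed) {
  stopifnot(inherits(T, "stochastic_matrix"), length >= 2)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  ns <- n_states(T)
  cum <- apply(T$probs, 2, cumsum)
  withr::with_seed(seed, {
    s0 <- if (identical(start, "stationary")) {
      pi <- stationary_distribution(T)
      sample.int(ns, 1, prob = pi)
    } else {
      stopifnot(start >= 0, start < ns)
      as.integer(start) + 1L
    }
    u <- stats::runif(length - 1)
    out <- integer(length)
    out[1] <- s0
    s <- s0
    for (i in seq_len(length - 1)) {
      s <- min(findInterval(u[i], cum[, s]) + 1L, ns)
      out[i + 1] <- s
    }
  })
  discrete_trajectory(out - 1L, dt = if (T$lag > 0) T$lag else 1)
}

#' Macrostate dwell times and transition path of a microstate trajectory
#'
#' Projects a microstate trajectory onto macrostates and run-length encodes
#' it. Dwells touching the trajectory boundaries cannot be observed in full
#' and are flagged censored (excluded from mean estimates by default
#' downstream).
#'
#' @param traj A [discrete_trajectory()] over microstates.
#' @param agg Aggregation sharing the microstate alphabet.
#' @return List with `dwells` (data frame: `state`, `duration`, `censored`)
#'   and `path` (the macro-to-macro visit sequence).
#' @export
macro_waiting_times <- function(traj, agg) {
  stopifnot(inherits(traj, "discrete_trajectory"), inherits(agg, "aggregation"))
  if (max(traj$labels) + 1 > nrow(agg$A)) {
    stop("DimensionMismatch: trajectory labels exceed aggregation alphabet",
         call. = FALSE)
  }
  macro <- agg$assignment[traj$labels + 1L]
  r <- rle(macro)
  nruns <- length(r$lengths)
  censored <- rep(FALSE, nruns)
  censored[1] <- TRUE
  censored[nruns] <- TRUE
  list(dwells = data.frame(state = agg$macro_labels[r$values],
                           duration = r$lengths * traj$dt,
                           censored = censored),
       path = agg$macro_labels[r$values])
}
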