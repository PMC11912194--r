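#' Chapman-Kolmogorov test against directly counted references
#'
#' Compares, state by state on a common time grid, the self-transition
#' probabilities `T[I, I](t)` predicted by one or more models against the
#' reference obtained by directly counting transitions in the trajectory
#' data at each grid time. A provider is a function `function(t)` returning
#' a [stochastic_matrix()] (or plain matrix) at time `t`; Markov powers,
#' qMSM propagation, hybrid models and constant estimators can all be
#' wrapped this way.
#'
#' @param trajs [trajectory_set()] over the (macro)states.
#' @param predictions Named list of provider functions.
#' @param grid Strictly positive times, multiples of `dt`, within the
#'   countable range.
#' @param full_matrix Also record off-diagonal deviations in the summary
#'   (default: diagonal elements only, the usual CK curves).
#' @param min_origins Passed to [transition_matrix_series()].
#' @return Object of class `ck_report`: list with `curves` (data frame
#'   `method`, `state`, `t`, `value`; method `"reference"` included) and
#'   `summary` (per method and state: `max_abs`, `rms` deviation from the
#'   reference).
#' @export
ck_test <- function(trajs, predictions, grid, full_matrix = FALSE,
                    min_origins = 100) {
  stopifnot(inherits(trajs, "trajectory_set"), length(predictions) > 0,
            !is.null(names(predictions)), all(grid > 0))
  ref <- tryCatch(
    transition_matrix_series(trajs, grid, min_origins = min_origins),
    error = function(e) {
      if (grepl("LagTooLong|InsufficientOrigins", conditionMessage(e))) {
        stop(sprintf("GridTooLong: %s", conditionMessage(e)), call. = FALSE)
      }
      stop(e)
    })
  ns <- n_states(ref[[1]])
  states <- seq_len(ns) - 1L
  curves <- data.frame()
  ref_diag <- t(vapply(ref, function(Tm) diag(as.matrix(Tm)), numeric(ns)))
  curves <- rbind(curves, data.frame(
    method = "reference",
    state = rep(states, each = length(grid)),
    t = rep(grid, ns),
    value = as.vector(ref_diag)))
  summ <- data.frame()
  for (nm in names(predictions)) {
    pred <- lapply(grid, function(tt) as.matrix(predictions[[nm]](tt)))
    pred_diag <- t(vapply(pred, diag, numeric(ns)))
    curves <- rbind(curves, data.frame(
      method = nm,
      state = rep(states, each = length(grid)),
      t = rep(grid, ns),
      value = as.vector(pred_diag)))
    for (s in seq_len(ns)) {
      dev <- if (full_matrix) {
        vapply(seq_along(grid),
               function(i) max(abs(pred[[i]][, s] - as.matrix(ref[[i]])[, s])), 0)
      } else {
        pred_diag[, s] - ref_diag[, s]
      }
      summ <- rbind(summ, data.frame(
        method = nm, state = s - 1L,
        max_abs = max(abs(dev)),
        rms = sqrt(mean(dev^2))))
    }
  }
  structure(list(curves = curves, summary = summ, full_matrix = full_matrix),
            class = "ck_report")
}

#' @export
print.ck_report <- function(x, ...) {
  cat("Chapman-Kolmogorov test\n")
  agg <- stats::aggregate(cbind(max_abs, rms) ~ method, x$summary, max)
  print(agg)
  invisible(x)
}

#' Population decay curve of a starting state
#'
#' `P(t)`: probability of still (or again) being in `start_state` at time
#' `t` when all probability starts there, i.e. the diagonal element
#' `T[start, start](t)`. `P(0) = 1`; for an ergodic model `P(t)` decays to
#' the equilibrium population.
#'
#' @param T_provider Function `function(t)` returning the transition matrix
#'   at time `t` (as [stochastic_matrix()] or plain matrix).
#' @param start_state 0-based state index.
#' @param grid Times (0 allowed).
#' @return Data frame with columns `t`, `P`.
#' @export
population_decay <- function(T_provider, start_state, grid) {
  i <- as.integer(start_state) + 1L
  P <- vapply(grid, function(tt) {
    if (tt == 0) return(1)
    as.matrix(T_provider(tt))[i, i]
  }, 0)
  data.frame(t = grid, P = P)
}

#' Sweep the estimator family across toy-model parameters
#'
#' For each parameter set, builds the toy microstate model and its L/R
#' lumping and reports the ratio of each macrostate estimator's slowest
#' implied timescale to the microstate reference `t_micro`: constant
#' estimators LE and HS, and the time-dependent microstate-based and qMSM
#' results evaluated at `eval_time` (where they should have plateaued; a
#' warning is emitted when the value at `2 * eval_time` still differs by
#' more than 1%).
#'
#' @param params_list List of [toy_params()] (a single one is accepted).
#' @param eval_time Evaluation time for the time-dependent methods
#'   (default 100).
#' @param kernel_threshold Normalized-kernel threshold for the qMSM kernel
#'   time (default 0.1).
#' @param check_plateau Verify the 1% plateau criterion (default TRUE).
#' @return Data frame with one row per parameter set: `h`, `k`, `h_over_k`,
#'   `t_micro`, and ratio columns `LE`, `HS`, `Mic`, `qMSM`.
#' @export
estimator_sweep <- function(params_list, eval_time = 100,
                            kernel_threshold = 0.1, check_plateau = TRUE) {
  if (inherits(params_list, "toy_params")) params_list <- list(params_list)
  rows <- lapply(params_list, function(p) {
    tm <- toy_micro_matrix(p)
    agg <- toy_macro_aggregation(p)
    t_micro <- slowest_timescale(tm)
    r_le <- slowest_timescale(lump_LE(agg, tm)) / t_micro
    r_hs <- slowest_timescale(lump_HS(agg, tm)) / t_micro
    m_eval <- as.integer(round(eval_time / p$tau0))
    mic_t <- function(m) slowest_timescale(lump_Mic(agg, tm, m))
    r_mic <- mic_t(m_eval) / t_micro
    q <- toy_qmsm_timescale(p, eval_time, kernel_threshold,
                            horizon = if (check_plateau) 2 * eval_time else eval_time)
    r_q <- q$at_eval / t_micro
    if (check_plateau) {
      if (abs(mic_t(2 * m_eval) - mic_t(m_eval)) > 0.01 * mic_t(m_eval)) {
        warning(sprintf("Mic timescale not plateaued at eval_time = %g (h = %g, k = %g)",
                        eval_time, p$h, p$k))
      }
      if (abs(q$at_double - q$at_eval) > 0.01 * abs(q$at_eval)) {
        warning(sprintf("qMSM timescale not plateaued at eval_time = %g (h = %g, k = %g)",
                        eval_time, p$h, p$k))
      }
    }
    data.frame(h = p$h, k = p$k, h_over_k = p$h / p$k, t_micro = t_micro,
               LE = r_le, HS = r_hs, Mic = r_mic, qMSM = r_q)
  })
  do.call(rbind, rows)
}

# exact-macrostate-series qMSM timescale for the toy model
toy_qmsm_timescale <- function(p, eval_time, kernel_threshold = 0.1,
                               horizon = NULL) {
  tm <- toy_micro_matrix(p)
  agg <- toy_macro_aggregation(p)
  n_train <- 200L  # ample for the toy kernel decay at any admissible (h, k)
  series <- project_series(agg, tm, n_train)
  K <- extract_kernel(series)
  tau_K <- select_kernel_time(K, threshold = kernel_threshold)
  horizon <- horizon %||% eval_time
  prop <- propagate_gme(series[seq_len(as.integer(tau_K / p$tau0) + 1)],
                        K, tau_K, horizon)
  ts_at <- function(tt) {
    idx <- as.integer(round(tt / p$tau0)) + 1L
    slowest_timescale(prop[[idx]])
  }
  list(tau_K = tau_K, at_eval = ts_at(eval_time),
       at_double = if (horizon >= 2 * eval_time) ts_at(2 * eval_time) else NA_real_,
       series = prop)
}
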