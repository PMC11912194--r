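#' Assemble a hybrid MD/MSM propagator
#'
#' Combines the approximation-free, directly counted series `T_MD(t)` at
#' short times with Markov powers of a single long-lag matrix beyond:
#' full time resolution where data exist, Markovianity bought with a long
#' lag where they do not. By default the long-lag matrix is the last entry
#' of the series itself (the direct count estimate at `t_max`), which makes
#' the propagator exactly continuous at the seam; any macrostate estimator
#' output ([lump_LE()], [lump_HS()], [lump_Mic()]) at lag `t_max` can be
#' supplied instead.
#'
#' @param T_MD_series List of [stochastic_matrix()] for `t = 0..t_max`
#'   (uniform spacing, identity first).
#' @param t_max Seam time; must equal the lag of the last series entry.
#' @param T_long Optional [stochastic_matrix()] with lag `t_max` used
#'   beyond the seam; defaults to `T_MD(t_max)`.
#' @return Object of class `hybrid_model`.
#' @export
build_hybrid <- function(T_MD_series, t_max, T_long = NULL) {
  stopifnot(length(T_MD_series) >= 2)
  check_series_start(T_MD_series)
  lags <- vapply(T_MD_series, function(x) x$lag, 0)
  dt <- lags[2] - lags[1]
  if (max(abs(diff(lags) - dt)) > 1e-9) {
    stop("T_MD_series must be uniformly spaced", call. = FALSE)
  }
  if (abs(lags[length(lags)] - t_max) > 1e-9) {
    stop(sprintf("LagMismatch: series ends at %g, t_max = %g",
                 lags[length(lags)], t_max), call. = FALSE)
  }
  T_long <- T_long %||% T_MD_series[[length(T_MD_series)]]
  stopifnot(inherits(T_long, "stochastic_matrix"))
  if (abs(T_long$lag - t_max) > 1e-9) {
    stop(sprintf("LagMismatch: T_long lag %g != t_max %g", T_long$lag, t_max),
         call. = FALSE)
  }
  if (n_states(T_long) != n_states(T_MD_series[[1]])) {
    stop("LagMismatch: T_long and series state spaces differ", call. = FALSE)
  }
  structure(list(T_MD_series = T_MD_series, T_long = T_long,
                 t_max = t_max, dt = dt),
            class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("hybrid_model: %d states, dt = %g, seam t_max = %g\n",
              n_states(x$T_long), x$dt, x$t_max))
  invisible(x)
}

#' Evaluate the hybrid propagator at a time
#'
#' For `t <= t_max` returns the stored `T_MD(t)` unchanged. For
#' `t = m * t_max + s` (`0 <= s < t_max`) it composes `m` long-lag Markov
#' blocks with the short-time remainder. The default order
#' (`"remainder_last"`) applies the long blocks chronologically first,
#' `T_MD(s) %*% T_long^m`, which keeps populations continuous in `s`
#' across each seam; `"remainder_first"` gives `T_long^m %*% T_MD(s)`.
#' Both agree at multiples of `t_max`.
#'
#' @param model A [build_hybrid()] result.
#' @param t Time, a non-negative multiple of the series step.
#' @param order Composition order for the mixed branch.
#' @return A [stochastic_matrix()] at lag `t`.
#' @export
hybrid_transition <- function(model, t,
                              order = c("remainder_last", "remainder_first")) {
  order <- match.arg(order)
  stopifnot(inherits(model, "hybrid_model"), t >= 0)
  nf <- t / model$dt
  if (abs(nf - round(nf)) > 1e-9) {
    stop(sprintf("TimeNotOnGrid: t = %g is not a multiple of dt = %g",
                 t, model$dt), call. = FALSE)
  }
  if (t <= model$t_max + 1e-9) {
    idx <- as.integer(round(nf)) + 1L
    return(model$T_MD_series[[idx]])
  }
  m <- floor((t + 1e-9) / model$t_max)
  s <- t - m * model$t_max
  long_part <- matpow(as.matrix(model$T_long), m)
  if (abs(s) < 1e-9) {
    M <- long_part
  } else {
    Ts <- as.matrix(model$T_MD_series[[as.integer(round(s / model$dt)) + 1L]])
    M <- if (order == "remainder_last") Ts %*% long_part else long_part %*% Ts
  }
  stochastic_matrix(M, lag = t, labels = model$T_long$labels, tol = 1e-8)
}
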