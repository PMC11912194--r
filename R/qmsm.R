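#' Initial time derivative of a transition-matrix series
#'
#' Forward difference anchored at the exactly known `T(0) = I`:
#' `Tdot0 = (T(dt) - I) / dt`. Its columns sum to zero (probability
#' conservation).
#'
#' @param T_series List of [stochastic_matrix()] starting with the identity
#'   at `t = 0`, at least two entries, uniformly spaced.
#' @param dt Series time step; defaults to the lag of the second entry.
#' @return Plain N x N matrix.
#' @export
initial_derivative <- function(T_series, dt = NULL) {
  if (length(T_series) < 2) stop("SeriesTooShort: need T(0) and T(dt)",
                                 call. = FALSE)
  check_series_start(T_series)
  dt <- dt %||% (T_series[[2]]$lag - T_series[[1]]$lag)
  (as.matrix(T_series[[2]]) - diag(n_states(T_series[[1]]))) / dt
}

check_series_start <- function(T_series) {
  T0 <- as.matrix(T_series[[1]])
  if (max(abs(T0 - diag(nrow(T0)))) > 1e-8) {
    stop("series must start with the identity at t = 0", call. = FALSE)
  }
  invisible(TRUE)
}

#' Extract the discretized memory kernel from a transition-matrix series
#'
#' Inverts the discretized generalized master equation
#' \deqn{T_{n+1} = T_n + \Delta t\,\dot T(0) T_n
#'   - \Delta t^2 \sum_{m=0}^{n} K_m T_{n-m}}
#' iteratively for the memory matrices `K_n`, `n = 0..n_max - 1`, where
#' `T_n` is the directly counted (or analytically projected) series
#' `T_MD(n * dt)`. With the `Tdot0` term kept, the discretization makes
#' `K_0` vanish identically (the term cancels the kernel at `t = 0`), and
#' for a Markovian series every `K_n` vanishes. When
#' `keep_Tdot0_term = FALSE` the `Tdot0 T(t)` term is dropped from the
#' equation; the flag is stored so that [propagate_gme()] stays consistent.
#'
#' @param T_series List of [stochastic_matrix()] covering `t = 0..n_max*dt`,
#'   starting with the identity.
#' @param dt Discretization step; defaults to the spacing of the series.
#' @param keep_Tdot0_term Keep the `Tdot0 T(t)` streaming term (default).
#' @return Object of class `memory_kernel_series`: list with `kernels`
#'   (list of N x N matrices `K_0..K_{n_max-1}`), `dt`, `Tdot0`,
#'   `keep_Tdot0_term`.
#' @export
extract_kernel <- function(T_series, dt = NULL, keep_Tdot0_term = TRUE) {
  if (length(T_series) < 2) stop("SeriesTooShort", call. = FALSE)
  check_series_start(T_series)
  dt <- dt %||% (T_series[[2]]$lag - T_series[[1]]$lag)
  Ts <- lapply(T_series, as.matrix)
  N <- nrow(Ts[[1]])
  Td0 <- (Ts[[2]] - diag(N)) / dt
  n_max <- length(Ts) - 1
  Ks <- vector("list", n_max)
  for (n in 0:(n_max - 1)) {
    base <- (Ts[[n + 1]] - Ts[[n + 2]]) / dt^2
    if (keep_Tdot0_term) base <- base + (Td0 %*% Ts[[n + 1]]) / dt
    S <- matrix(0, N, N)
    if (n > 0) for (m in 0:(n - 1)) S <- S + Ks[[m + 1]] %*% Ts[[n - m + 1]]
    Kn <- base - S
    if (!all(is.finite(Kn))) {
      stop(sprintf("NonInvertible: kernel solve failed at n = %d", n),
           call. = FALSE)
    }
    Ks[[n + 1]] <- Kn
  }
  structure(list(kernels = Ks, dt = dt, Tdot0 = Td0,
                 keep_Tdot0_term = keep_Tdot0_term),
            class = "memory_kernel_series")
}

#' @export
print.memory_kernel_series <- function(x, ...) {
  cat(sprintf("memory_kernel_series: %d kernels, dt = %g, Tdot0 term %s\n",
              length(x$kernels), x$dt,
              if (x$keep_Tdot0_term) "kept" else "dropped"))
  nk <- kernel_decay_profile(x)
  if (length(nk) > 0) {
    cat("max |normalized kernel| per step:\n")
    print(round(utils::head(nk, 10), 4))
  }
  invisible(x)
}

#' Normalized memory kernel element
#'
#' The series `K[I, J](n * dt) / K[I, J](dt)` for `n >= 1`, so the value at
#' the first step is exactly one. This is the curve used to judge how fast
#' the memory decays.
#'
#' @param K A [extract_kernel()] result.
#' @param element Integer pair `(I, J)` selecting the kernel element
#'   (default `c(1, 1)`, the `LL` element).
#' @return Data frame with columns `n`, `t`, `value`.
#' @export
normalized_kernel <- function(K, element = c(1, 1)) {
  stopifnot(inherits(K, "memory_kernel_series"), length(element) == 2)
  if (length(K$kernels) < 2) stop("SeriesTooShort: no kernel at t = dt",
                                  call. = FALSE)
  denom <- K$kernels[[2]][element[1], element[2]]
  if (denom == 0) stop("ZeroNormalizer: K(dt) element is zero", call. = FALSE)
  n <- seq_len(length(K$kernels) - 1)
  vals <- vapply(n, function(i) K$kernels[[i + 1]][element[1], element[2]] / denom, 0)
  data.frame(n = n, t = n * K$dt, value = vals)
}

# element-wise max |K_n / K_1| for n = 1.., with a guard for K_1 entries
# whose magnitude is negligible relative to the largest one (those are
# normalized by the largest magnitude instead)
kernel_decay_profile <- function(K) {
  if (length(K$kernels) < 2) return(numeric(0))
  K1 <- K$kernels[[2]]
  scale <- max(abs(K1))
  if (scale == 0) return(rep(0, length(K$kernels) - 1))
  denom <- abs(K1)
  denom[denom < 1e-10 * scale] <- scale
  vapply(seq_len(length(K$kernels) - 1),
         function(n) max(abs(K$kernels[[n + 1]]) / denom), 0)
}

#' Select the kernel decay time tau_K
#'
#' Returns the smallest time `n * dt` (searching from `n = 1`) at which the
#' element-wise maximum of the normalized kernel has decayed to
#' `<= threshold` and stays there for `persistence` recorded steps (to
#' tolerate residual fluctuations around zero in noisy kernels). An
#' identically vanishing kernel (the exactly Markovian case) returns `dt`,
#' the earliest possible time.
#'
#' @param K A [extract_kernel()] result.
#' @param threshold Decay threshold on the normalized kernel (default 0.1).
#' @param persistence Number of consecutive recorded steps that must
#'   satisfy the threshold (default 3; truncated at the series end).
#' @return The kernel time `tau_K` (same unit as `dt`).
#' @export
select_kernel_time <- function(K, threshold = 0.1, persistence = 3) {
  stopifnot(inherits(K, "memory_kernel_series"))
  prof <- kernel_decay_profile(K)
  if (length(prof) == 0 || all(prof == 0)) return(K$dt)
  n_last <- length(prof)
  for (n in seq_len(n_last)) {
    window <- n:min(n + persistence - 1, n_last)
    if (all(prof[window] <= threshold)) return(n * K$dt)
  }
  stop(sprintf("ThresholdNeverMet: min max-normalized kernel %.4g > %g",
               min(prof), threshold), call. = FALSE)
}

#' Propagate the generalized master equation with a truncated kernel
#'
#' Advances the transition matrix beyond the data window via
#' \deqn{T_{n+1} = T_n + \Delta t\,\dot T(0) T_n
#'   - \Delta t^2 \sum_{m=0}^{\min(n, n_K - 1)} K_m T_{n-m}}
#' with `n_K = tau_K / dt`. The kernel sum is a left-endpoint rule over
#' `[0, tau_K)`: kernels at times below `tau_K` enter, the one at `tau_K`
#' (decayed below threshold by construction of [select_kernel_time()]) does
#' not. Given a short series (down to just `T(0), T(dt)`) the recurrence
#' regenerates the training window exactly, since [extract_kernel()] is its
#' exact inverse. Propagated columns are renormalized when their sums drift
#' from one by less than `1e-6` (with a warning beyond `1e-10`); larger
#' drift, or any entry outside `[-0.1, 1.1]`, aborts - a noise-amplified
#' kernel should fail loudly rather than be silently renormalized.
#'
#' @param T_short List of [stochastic_matrix()] from `t = 0` (identity) up
#'   to at most `tau_K`; at least `T(0)` and `T(dt)`.
#' @param K A [extract_kernel()] result (its `keep_Tdot0_term` flag and
#'   `Tdot0` are used for consistency with the extraction).
#' @param tau_K Kernel truncation time, a positive multiple of `dt`; needs
#'   `tau_K / dt` extracted kernels.
#' @param horizon Final time of the propagation, `> tau_K`.
#' @return List of [stochastic_matrix()] for `t = 0..horizon` in steps of
#'   `dt` (the given entries first, propagated ones after).
#' @export
propagate_gme <- function(T_short, K, tau_K, horizon) {
  stopifnot(inherits(K, "memory_kernel_series"))
  if (length(T_short) < 2) stop("SeriesTooShort", call. = FALSE)
  check_series_start(T_short)
  dt <- K$dt
  nK <- tau_K / dt
  if (abs(nK - round(nK)) > 1e-9 || nK < 1) {
    stop("tau_K must be a positive multiple of dt", call. = FALSE)
  }
  nK <- as.integer(round(nK))
  if (nK > length(K$kernels)) {
    stop(sprintf("tau_K = %g needs %d kernels, only %d extracted",
                 tau_K, nK, length(K$kernels)), call. = FALSE)
  }
  n_hor <- as.integer(round(horizon / dt))
  if (n_hor * dt <= tau_K) stop("horizon must exceed tau_K", call. = FALSE)
  Ts <- lapply(T_short, as.matrix)
  if (length(Ts) > nK + 1) Ts <- Ts[seq_len(nK + 1)]
  N <- nrow(Ts[[1]])
  labels <- T_short[[1]]$labels
  warned <- FALSE
  for (n in (length(Ts) - 1):(n_hor - 1)) {
    S <- matrix(0, N, N)
    for (m in 0:min(n, nK - 1)) S <- S + K$kernels[[m + 1]] %*% Ts[[n - m + 1]]
    Tn1 <- Ts[[n + 1]] - dt^2 * S
    if (K$keep_Tdot0_term) Tn1 <- Tn1 + dt * (K$Tdot0 %*% Ts[[n + 1]])
    if (any(Tn1 < -0.1) || any(Tn1 > 1.1)) {
      stop(sprintf("Blowup: propagated entry outside [-0.1, 1.1] at t = %g",
                   (n + 1) * dt), call. = FALSE)
    }
    drift <- max(abs(colSums(Tn1) - 1))
    if (drift >= 1e-6) {
      stop(sprintf("column sums drift by %g at t = %g (>= 1e-6)",
                   drift, (n + 1) * dt), call. = FALSE)
    }
    if (drift > 1e-10 && !warned) {
      warning(sprintf("renormalizing propagated columns (drift up to %g)", drift))
      warned <- TRUE
    }
    Ts[[n + 2]] <- sweep(Tn1, 2, colSums(Tn1), "/")
  }
  lapply(seq_along(Ts) - 1, function(n) {
    stochastic_matrix(Ts[[n + 1]], lag = n * dt, labels = labels, tol = 1e-6)
  })
}
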