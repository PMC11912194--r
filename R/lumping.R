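#' Micro-to-macrostate aggregation
#'
#' Bundles everything needed to project microstate dynamics onto
#' macrostates: the 0/1 aggregation matrix `A` (`A[i, J] = 1` iff
#' microstate `i` belongs to macrostate `J`), the microstate equilibrium
#' populations `pi`, the macrostate populations `Pi = t(A) %*% pi`, and the
#' normalized aggregation `A_hat = D_n A D_N^{-1}` whose column `J` is the
#' equilibrium distribution *within* macrostate `J` (each column sums to
#' one). `t(A) %*% A_hat` is the identity.
#'
#' @param t_micro Microstate [stochastic_matrix()] (n states).
#' @param assignment Micro-to-macro map: either an integer/character vector
#'   of length n (macrostate of each microstate, in microstate order), or a
#'   two-column data frame `(microstate, macrostate)` with 0-based or
#'   1-based microstate indices covering all states.
#' @param pi Optional microstate equilibrium populations; defaults to
#'   [stationary_distribution()] of `t_micro` (self-consistent choice for
#'   equilibrium-sampled data). Supply empirical frame frequencies here to
#'   use an observed distribution instead.
#' @return Object of class `aggregation`: list with `assignment` (integer,
#'   1-based), `macro_labels`, `A`, `A_hat`, `micro_pi`, `macro_Pi`.
#' @examples
#' p <- toy_params(0.1, 0.1)
#' build_aggregation(toy_micro_matrix(p), c("L", "L", "R", "R"))
#' @export
build_aggregation <- function(t_micro, assignment, pi = NULL) {
  stopifnot(inherits(t_micro, "stochastic_matrix"))
  n <- n_states(t_micro)
  if (is.data.frame(assignment)) {
    micro <- as.integer(assignment[[1]])
    if (min(micro) == 0L) micro <- micro + 1L
    if (!setequal(micro, seq_len(n))) {
      stop("assignment must cover every microstate exactly once", call. = FALSE)
    }
    assignment <- assignment[[2]][order(micro)]
  }
  if (length(assignment) != n) {
    stop(sprintf("assignment covers %d microstates, matrix has %d",
                 length(assignment), n), call. = FALSE)
  }
  if (anyNA(assignment)) stop("assignment contains missing values", call. = FALSE)
  macro_labels <- as.character(sort(unique(assignment)))
  N <- length(macro_labels)
  if (N < 2) stop("need at least 2 macrostates", call. = FALSE)
  idx <- match(as.character(assignment), macro_labels)
  if (any(tabulate(idx, N) == 0)) {
    stop("EmptyMacrostate: every macrostate must contain a microstate",
         call. = FALSE)
  }
  A <- matrix(0, n, N)
  A[cbind(seq_len(n), idx)] <- 1
  if (is.null(pi)) {
    pi <- stationary_distribution(t_micro)
  } else {
    stopifnot(length(pi) == n, all(pi > 0))
    pi <- pi / sum(pi)
  }
  Pi <- drop(t(A) %*% pi)
  A_hat <- diag(pi) %*% A %*% diag(1 / Pi, N)
  names(Pi) <- macro_labels
  structure(list(assignment = idx, macro_labels = macro_labels,
                 A = A, A_hat = A_hat,
                 micro_pi = unname(pi), macro_Pi = Pi),
            class = "aggregation")
}

#' @export
print.aggregation <- function(x, ...) {
  cat(sprintf("aggregation: %d microstates -> %d macrostates (%s)\n",
              nrow(x$A), ncol(x$A), paste(x$macro_labels, collapse = ", ")))
  cat("macrostate populations:\n")
  print(round(x$macro_Pi, 6))
  invisible(x)
}

#' Read a micro-to-macro assignment table
#'
#' Two-column CSV `(microstate, macrostate)`; a header line is detected
#' automatically.
#'
#' @param path CSV path.
#' @return Two-column data frame suitable for [build_aggregation()].
#' @export
read_assignment <- function(path) {
  first <- readLines(path, n = 1)
  header <- !grepl("^\\s*[0-9]+\\s*,", first)
  df <- utils::read.csv(path, header = header)
  if (ncol(df) < 2) stop("assignment table needs two columns", call. = FALSE)
  df[, 1:2]
}

#' Project microstate populations onto macrostates
#'
#' `P = t(A) %*% p`: macrostate populations are sums of their microstate
#' populations, so total probability is preserved.
#'
#' @param agg An [build_aggregation()] result.
#' @param p Microstate population vector (non-negative, sums to one).
#' @return Named macrostate population vector.
#' @export
project_populations <- function(agg, p) {
  stopifnot(inherits(agg, "aggregation"))
  if (length(p) != nrow(agg$A)) {
    stop("DimensionMismatch: population vector length != number of microstates",
         call. = FALSE)
  }
  stats::setNames(drop(t(agg$A) %*% p), agg$macro_labels)
}

#' Local-equilibrium macrostate transition matrix
#'
#' The one-step flux-matching projection `T_LE = t(A) %*% t %*% A_hat`,
#' equivalent to counting macrostate transitions directly: it satisfies
#' `T[I, J] * Pi[J] = sum over i in I, j in J of t[i, j] * pi[j]`. It
#' assumes instantaneous equilibration within each macrostate and yields a
#' constant (lag-only) matrix whose stationary distribution is `Pi`.
#'
#' @param agg Aggregation built from `t_micro`.
#' @param t_micro Microstate [stochastic_matrix()].
#' @return Macrostate [stochastic_matrix()] at the same lag.
#' @export
lump_LE <- function(agg, t_micro) {
  check_agg_matrix(agg, t_micro)
  M <- t(agg$A) %*% t_micro$probs %*% agg$A_hat
  stochastic_matrix(M, lag = t_micro$lag, labels = agg$macro_labels,
                    tol = 1e-8)
}

#' Microstate-based macrostate transition matrix
#'
#' Propagates the microstate model first and projects afterwards:
#' `T_Mic(m * tau) = t(A) %*% t^m %*% A_hat`. Because the microstate model
#' is assumed Markovian, this preserves all its dynamical content and gives
#' exact macrostate population dynamics for initial conditions equilibrated
#' within each macrostate; the price is a genuinely time-dependent matrix
#' (`T_Mic(m*tau)` is generally not `T_Mic(tau)^m`). At `m = 1` it equals
#' [lump_LE()].
#'
#' @param agg Aggregation built from `t_micro`.
#' @param t_micro Microstate [stochastic_matrix()].
#' @param m Positive integer number of microstate lag steps.
#' @return Macrostate [stochastic_matrix()] at lag `m * lag`.
#' @export
lump_Mic <- function(agg, t_micro, m) {
  check_agg_matrix(agg, t_micro)
  stopifnot(m >= 1, m == round(m))
  M <- t(agg$A) %*% matpow(t_micro$probs, m) %*% agg$A_hat
  stochastic_matrix(M, lag = m * t_micro$lag, labels = agg$macro_labels,
                    tol = 1e-8)
}

#' Series of microstate-based macrostate matrices
#'
#' `T_Mic(m * tau)` for `m = 0..n_max` (the `m = 0` entry is the identity).
#' This is the exact macrostate `T_MD(t)` series of a model whose
#' microstates are Markovian, and is the noiseless input for
#' [extract_kernel()] on analytic models.
#'
#' @param agg Aggregation built from `t_micro`.
#' @param t_micro Microstate [stochastic_matrix()].
#' @param n_max Largest number of lag steps.
#' @return List of `n_max + 1` macrostate [stochastic_matrix()] objects.
#' @export
project_series <- function(agg, t_micro, n_max) {
  check_agg_matrix(agg, t_micro)
  N <- ncol(agg$A)
  out <- vector("list", n_max + 1)
  out[[1]] <- stochastic_matrix(diag(N), lag = 0, labels = agg$macro_labels)
  tp <- diag(nrow(agg$A))
  for (m in seq_len(n_max)) {
    tp <- tp %*% t_micro$probs
    out[[m + 1]] <- stochastic_matrix(t(agg$A) %*% tp %*% agg$A_hat,
                                      lag = m * t_micro$lag,
                                      labels = agg$macro_labels, tol = 1e-8)
  }
  out
}

#' Hummer-Szabo macrostate transition matrix
#'
#' The optimal long-time projection of the microstate dynamics onto the
#' macrostates, obtained by matching the summed (Laplace-transformed)
#' propagator at its long-time singularity:
#' \deqn{T_{HS} = I_N + \Pi 1^T - [A^T (I_n - t + \pi 1^T)^{-1} \hat A]^{-1}}
#' It is a constant matrix, preserves `Pi`, and reduces to `t_micro`
#' exactly under the identity aggregation; it requires one n-dimensional
#' and one N-dimensional inversion. Column sums are exact analytically;
#' numerical drift up to `1e-8` is renormalized with a warning, larger
#' drift is an error.
#'
#' @param agg Aggregation built from `t_micro`.
#' @param t_micro Microstate [stochastic_matrix()].
#' @return Macrostate [stochastic_matrix()] at the same lag.
#' @export
lump_HS <- function(agg, t_micro) {
  check_agg_matrix(agg, t_micro)
  n <- n_states(t_micro)
  N <- ncol(agg$A)
  Z <- diag(n) - t_micro$probs + agg$micro_pi %*% t(rep(1, n))
  rc <- rcond(Z)
  if (rc < 1e-14) {
    stop(sprintf("SingularMatrix: fundamental matrix has rcond = %g", rc),
         call. = FALSE)
  }
  M <- t(agg$A) %*% solve(Z, agg$A_hat)
  rcM <- rcond(M)
  if (rcM < 1e-14) {
    stop(sprintf("SingularMatrix: projected resolvent has rcond = %g", rcM),
         call. = FALSE)
  }
  Ths <- diag(N) + agg$macro_Pi %*% t(rep(1, N)) - solve(M)
  drift <- max(abs(colSums(Ths) - 1))
  if (drift > 1e-8) {
    stop(sprintf("Hummer-Szabo columns drift from 1 by %g (> 1e-8)", drift),
         call. = FALSE)
  }
  if (drift > 1e-12) {
    warning(sprintf("renormalizing Hummer-Szabo columns (drift %g)", drift))
    Ths <- sweep(Ths, 2, colSums(Ths), "/")
  }
  stochastic_matrix(Ths, lag = t_micro$lag, labels = agg$macro_labels,
                    tol = 1e-8)
}

check_agg_matrix <- function(agg, t_micro) {
  stopifnot(inherits(agg, "aggregation"), inherits(t_micro, "stochastic_matrix"))
  if (nrow(agg$A) != n_states(t_micro)) {
    stop("DimensionMismatch: aggregation and matrix disagree on microstate count",
         call. = FALSE)
  }
  invisible(TRUE)
}
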