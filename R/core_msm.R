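#' Construct and validate a column-stochastic transition matrix
#'
#' A `stochastic_matrix` holds the transition probabilities `T[i, j]` of
#' jumping from state `j` to state `i` within the lag time, so that
#' populations evolve as `P(t) = T %*% P(0)` and every *column* sums to one.
#' The column-stochastic convention is used throughout the package;
#' row-stochastic input (the other common convention) can be converted at
#' this boundary with `row_stochastic = TRUE`.
#'
#' @param probs Square numeric matrix of transition probabilities.
#' @param lag Lag time of the matrix, in the time unit of the trajectory
#'   (`lag = 0` is allowed only for the trivial identity entry of a
#'   time-dependent series, e.g. `T(0)` in [transition_matrix_series()]).
#' @param labels Optional character vector of state names.
#' @param tol Numerical tolerance for the stochasticity check: column sums
#'   must lie within `tol` of 1 and entries within `[-tol, 1 + tol]`
#'   (entries are then clipped to `[0, 1]`).
#' @param row_stochastic If `TRUE`, `probs` is interpreted as row-stochastic
#'   and transposed on input.
#'
#' @return An object of class `stochastic_matrix`: a list with elements
#'   `probs`, `lag` and `labels`.
#' @examples
#' stochastic_matrix(matrix(c(0.9, 0.1, 0.1, 0.9), 2), lag = 1)
#' @export
stochastic_matrix <- function(probs, lag = 1, labels = NULL, tol = 1e-10,
                              row_stochastic = FALSE) {
  probs <- as.matrix(probs)
  if (nrow(probs) != ncol(probs)) {
    stop("NotStochastic: matrix must be square", call. = FALSE)
  }
  if (!all(is.finite(probs))) {
    stop("NotStochastic: entries must be finite", call. = FALSE)
  }
  if (row_stochastic) probs <- t(probs)
  if (any(probs < -tol) || any(probs > 1 + tol)) {
    stop(sprintf("NegativeEntry: entries outside [0, 1] beyond tol = %g", tol),
         call. = FALSE)
  }
  csums <- colSums(probs)
  if (any(abs(csums - 1) > tol)) {
    stop(sprintf(
      "NotStochastic: column sums deviate from 1 by up to %g (tol = %g)",
      max(abs(csums - 1)), tol), call. = FALSE)
  }
  probs <- pmin(pmax(probs, 0), 1)
  if (!is.numeric(lag) || length(lag) != 1 || lag < 0) {
    stop("lag must be a single non-negative number", call. = FALSE)
  }
  if (!is.null(labels)) {
    stopifnot(length(labels) == nrow(probs))
    dimnames(probs) <- list(labels, labels)
  }
  structure(list(probs = probs, lag = lag, labels = labels),
            class = "stochastic_matrix")
}

#' @export
as.matrix.stochastic_matrix <- function(x, ...) x$probs

#' @export
print.stochastic_matrix <- function(x, ...) {
  cat(sprintf("stochastic_matrix: %d states, lag = %g\n", nrow(x$probs), x$lag))
  print(round(x$probs, 6))
  invisible(x)
}

#' Number of states of a stochastic matrix
#' @param T A [stochastic_matrix()].
#' @return Integer number of states.
#' @export
n_states <- function(T) nrow(T$probs)

#' Stationary distribution of a transition matrix
#'
#' Returns the equilibrium populations `pi`, i.e. the eigenvector of the
#' unit eigenvalue normalized to sum one. The chain must be irreducible
#' (one communicating class); a transition matrix with several closed
#' classes has a degenerate unit eigenvalue and is rejected.
#'
#' @param T A [stochastic_matrix()].
#' @return Numeric vector of positive probabilities summing to one.
#' @examples
#' stationary_distribution(stochastic_matrix(matrix(c(0.9, 0.1, 0.1, 0.9), 2)))
#' @export
stationary_distribution <- function(T) {
  stopifnot(inherits(T, "stochastic_matrix"))
  ev <- eigen(T$probs)
  vals <- ev$values
  unit <- which(abs(vals - 1) < 1e-8)
  if (length(unit) == 0) {
    stop("Disconnected: no unit eigenvalue found", call. = FALSE)
  }
  if (sum(Mod(vals) >= 1 - 1e-10) > 1) {
    stop("Disconnected: multiple closed communicating classes", call. = FALSE)
  }
  v <- Re(ev$vectors[, unit[1]])
  v <- v / sum(v)
  if (any(v <= 0)) {
    stop("Disconnected: stationary vector has non-positive entries",
         call. = FALSE)
  }
  names(v) <- T$labels
  v
}

#' Chapman-Kolmogorov power of a transition matrix
#'
#' Computes `T^m`, the Markov prediction for the transition matrix at
#' `m` times the lag, by repeated squaring.
#'
#' @param T A [stochastic_matrix()].
#' @param m Positive integer power.
#' @return A [stochastic_matrix()] with lag `m * lag`.
#' @export
propagate_power <- function(T, m) {
  stopifnot(inherits(T, "stochastic_matrix"))
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != round(m)) {
    stop("m must be a positive integer", call. = FALSE)
  }
  P <- matpow(T$probs, m)
  stochastic_matrix(P, lag = m * T$lag, labels = T$labels, tol = 1e-8)
}

# matrix power by repeated squaring (plain matrices)
matpow <- function(A, m) {
  R <- diag(nrow(A))
  B <- A
  while (m > 0) {
    if (m %% 2 == 1) R <- R %*% B
    m <- m %/% 2
    if (m > 0) B <- B %*% B
  }
  R
}

#' Implied timescales of a transition matrix
#'
#' For every nonstationary eigenvalue `lambda` the implied timescale is
#' `-lag / log(|lambda|)`. The single stationary eigenvalue (1) is removed;
#' any further eigenvalue with modulus within `1e-12` of one yields an
#' infinite timescale and a warning (a sign of a disconnected model).
#' Using the modulus makes negative eigenvalues (possible for strongly
#' non-Markovian projections) and complex pairs (possible for
#' non-reversible estimates, warned about) give finite timescales; a zero
#' modulus maps to timescale 0.
#'
#' @param T A [stochastic_matrix()].
#' @return An object of class `timescale_spectrum`: list with `timescales`
#'   (sorted descending) and the corresponding `eigenvalues` (sorted by
#'   modulus descending, ties broken by real part).
#' @examples
#' implied_timescales(stochastic_matrix(matrix(c(0.75, 0.25, 0.25, 0.75), 2)))
#' @export
implied_timescales <- function(T) {
  stopifnot(inherits(T, "stochastic_matrix"))
  vals <- eigen(T$probs, only.values = TRUE)$values
  ord <- order(-Mod(vals), -Re(vals))
  vals <- vals[ord]
  # drop the single stationary eigenvalue (closest to 1)
  stat_idx <- which.min(Mod(vals - 1))
  vals <- vals[-stat_idx]
  if (any(Im(vals) != 0 & Mod(Im(vals)) > 1e-12)) {
    warning("complex eigenvalue pair(s): using modulus for timescales")
  }
  mods <- Mod(vals)
  ts <- ifelse(mods >= 1 - 1e-12, Inf,
               ifelse(mods == 0, 0, -T$lag / log(mods)))
  if (any(is.infinite(ts))) {
    warning("MultipleUnitEigenvalues: non-stationary eigenvalue(s) with |lambda| ~ 1")
  }
  structure(list(timescales = ts, eigenvalues = vals),
            class = "timescale_spectrum")
}

#' @export
print.timescale_spectrum <- function(x, ...) {
  cat("implied timescales:\n")
  print(data.frame(timescale = x$timescales,
                   eigenvalue = format(x$eigenvalues, digits = 6)))
  invisible(x)
}

#' Slowest implied timescale
#'
#' Convenience accessor for the longest (nontrivial) implied timescale.
#'
#' @param T A [stochastic_matrix()].
#' @return Single numeric timescale.
#' @export
slowest_timescale <- function(T) implied_timescales(T)$timescales[1]

#' Write a transition matrix as CSV with a key-value sidecar
#'
#' The matrix is written headerless at full precision; `path` gains a
#' `.meta` sidecar recording the lag, the storage convention and the state
#' labels so the matrix can be read back losslessly.
#'
#' @param T A [stochastic_matrix()].
#' @param path Output CSV path.
#' @param row_stochastic Write the transpose (row-stochastic convention).
#' @param extra Named character vector of extra sidecar fields (e.g. the
#'   estimator method).
#' @return `path`, invisibly.
#' @export
write_stochastic_matrix <- function(T, path, row_stochastic = FALSE,
                                    extra = NULL) {
  stopifnot(inherits(T, "stochastic_matrix"))
  M <- if (row_stochastic) t(T$probs) else T$probs
  utils::write.table(format(M, digits = 17, scientific = TRUE, trim = TRUE),
                     path, sep = ",", row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  meta <- c(lag = as.character(T$lag),
            convention = if (row_stochastic) "row" else "column",
            labels = paste(T$labels %||% character(), collapse = ";"),
            extra)
  writeLines(paste(names(meta), meta, sep = ": "), paste0(path, ".meta"))
  invisible(path)
}

#' Read a transition matrix written by [write_stochastic_matrix()]
#'
#' @param path CSV path; the `.meta` sidecar is consulted when present.
#' @param row_stochastic Override: interpret the file as row-stochastic.
#'   Ignored when a sidecar states the convention.
#' @param tol Validation tolerance passed to [stochastic_matrix()].
#' @return A [stochastic_matrix()].
#' @export
read_stochastic_matrix <- function(path, row_stochastic = FALSE, tol = 1e-8) {
  M <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(M) <- NULL
  lag <- 1
  labels <- NULL
  meta_path <- paste0(path, ".meta")
  if (file.exists(meta_path)) {
    kv <- read_sidecar(meta_path)
    if (!is.null(kv[["lag"]])) lag <- as.numeric(kv[["lag"]])
    if (!is.null(kv[["convention"]])) {
      row_stochastic <- identical(kv[["convention"]], "row")
    }
    if (!is.null(kv[["labels"]]) && nzchar(kv[["labels"]])) {
      labels <- strsplit(kv[["labels"]], ";", fixed = TRUE)[[1]]
    }
  }
  stochastic_matrix(M, lag = lag, labels = labels, tol = tol,
                    row_stochastic = row_stochastic)
}

read_sidecar <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  out <- lapply(kv, function(m) m[3])
  names(out) <- vapply(kv, function(m) m[2], "")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
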