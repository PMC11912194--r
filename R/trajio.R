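#' Discrete state trajectory
#'
#' A sequence of integer state labels sampled at a uniform time step `dt`.
#' Labels are 0-based dense indices internally; any original labels are
#' kept in the `state_map` attribute of the containing [trajectory_set()].
#'
#' @param labels Integer vector of state indices (non-negative), length >= 2.
#' @param dt Frame spacing (time units), > 0.
#' @return Object of class `discrete_trajectory`.
#' @export
discrete_trajectory <- function(labels, dt = 1) {
  labels <- as.integer(labels)
  if (length(labels) < 2) stop("trajectory must have at least 2 frames", call. = FALSE)
  if (anyNA(labels) || any(labels < 0)) {
    stop("ParseError: labels must be non-negative integers", call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1 || dt <= 0) {
    stop("dt must be a single positive number", call. = FALSE)
  }
  structure(list(labels = labels, dt = dt), class = "discrete_trajectory")
}

#' @export
print.discrete_trajectory <- function(x, ...) {
  cat(sprintf("discrete_trajectory: %d frames, dt = %g, %d states observed\n",
              length(x$labels), x$dt, length(unique(x$labels))))
  invisible(x)
}

#' Set of trajectories over a common state alphabet
#'
#' @param trajectories List of [discrete_trajectory()] objects sharing `dt`.
#' @param state_map Optional named integer vector mapping original labels to
#'   the dense 0-based alphabet (names = original labels).
#' @return Object of class `trajectory_set`.
#' @export
trajectory_set <- function(trajectories, state_map = NULL) {
  if (inherits(trajectories, "discrete_trajectory")) {
    trajectories <- list(trajectories)
  }
  if (length(trajectories) == 0) stop("empty trajectory set", call. = FALSE)
  stopifnot(all(vapply(trajectories, inherits, TRUE, "discrete_trajectory")))
  dts <- vapply(trajectories, function(x) x$dt, 0)
  if (length(unique(dts)) != 1) {
    stop("all trajectories must share the same dt", call. = FALSE)
  }
  structure(list(trajectories = trajectories, dt = dts[1],
                 state_map = state_map),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat(sprintf("trajectory_set: %d trajectories, %d total frames, dt = %g, %d states\n",
              length(x$trajectories),
              sum(vapply(x$trajectories, function(t) length(t$labels), 0L)),
              x$dt, n_states_observed(x)))
  invisible(x)
}

n_states_observed <- function(trajs) {
  max(vapply(trajs$trajectories, function(t) max(t$labels), 0L)) + 1L
}

#' Read discrete state trajectories from text files
#'
#' Each file holds one integer state label per line (or one CSV column
#' selected with `column`). Gzip-compressed files are read transparently.
#' Labels across all files are re-indexed to a dense 0-based alphabet; the
#' original-to-dense map is retained in the returned set's `state_map`.
#'
#' @param paths Character vector of file paths.
#' @param dt Frame spacing (time units).
#' @param column Optional CSV column (name or index) holding the labels; if
#'   `NULL`, files are plain one-label-per-line text.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(paths, dt = 1, column = NULL) {
  stopifnot(length(paths) >= 1)
  raw <- lapply(paths, function(p) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p), call. = FALSE)
    if (is.null(column)) {
      con <- if (grepl("\\.gz$", p)) gzfile(p) else file(p)
      lines <- readLines(con)
      close(con)
      lines <- trimws(lines)
      lines <- lines[nzchar(lines)]
      if (length(lines) == 0) stop(sprintf("EmptyFile: %s", p), call. = FALSE)
      vals <- suppressWarnings(as.integer(lines))
      if (anyNA(vals)) {
        bad <- lines[which(is.na(vals))[1]]
        stop(sprintf("ParseError: non-integer token '%s' in %s", bad, p),
             call. = FALSE)
      }
      vals
    } else {
      df <- utils::read.csv(p)
      if (nrow(df) == 0) stop(sprintf("EmptyFile: %s", p), call. = FALSE)
      col <- df[[column]]
      if (is.null(col)) stop(sprintf("column '%s' not found in %s", column, p),
                             call. = FALSE)
      vals <- suppressWarnings(as.integer(col))
      if (anyNA(vals)) stop(sprintf("ParseError: non-integer token in %s", p),
                            call. = FALSE)
      vals
    }
  })
  alphabet <- sort(unique(unlist(raw)))
  state_map <- stats::setNames(seq_along(alphabet) - 1L, alphabet)
  trajs <- lapply(raw, function(v) {
    discrete_trajectory(state_map[as.character(v)], dt = dt)
  })
  trajectory_set(trajs, state_map = state_map)
}

#' Write a discrete trajectory as plain text (one label per line)
#'
#' @param traj A [discrete_trajectory()].
#' @param path Output path (gzipped when ending in `.gz`).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  writeLines(as.character(traj$labels), con)
  close(con)
  invisible(path)
}

#' Count state-to-state transitions at a lag time
#'
#' Entry `(i, j)` of the count matrix is the number of observed transitions
#' from state `j` to state `i` within the lag (column = origin state, the
#' package-wide convention). Sliding mode counts every frame pair
#' `(t, t + lag)`; strided mode counts non-overlapping pairs. Pairs never
#' cross trajectory boundaries.
#'
#' @param trajs A [trajectory_set()].
#' @param lag Lag time, a positive multiple of `dt`.
#' @param mode `"sliding"` (default) or `"strided"`.
#' @param n_states Alphabet size; defaults to the largest observed label + 1.
#' @return Object of class `count_matrix`: list with integer matrix
#'   `counts` and `lag`.
#' @export
count_transitions <- function(trajs, lag, mode = c("sliding", "strided"),
                              n_states = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(trajs, "trajectory_set"))
  lf <- lag_frames(lag, trajs$dt)
  ns <- n_states %||% n_states_observed(trajs)
  C <- matrix(0L, ns, ns)
  for (tr in trajs$trajectories) {
    n <- length(tr$labels)
    if (n <= lf) {
      stop(sprintf("LagTooLong: trajectory with %d frames at lag of %d frames",
                   n, lf), call. = FALSE)
    }
    origins <- if (mode == "sliding") seq_len(n - lf) else seq(1, n - lf, by = lf)
    from <- tr$labels[origins] + 1L
    to <- tr$labels[origins + lf] + 1L
    tab <- table(factor(to, levels = seq_len(ns)),
                 factor(from, levels = seq_len(ns)))
    C <- C + unclass(tab)
  }
  dimnames(C) <- NULL
  structure(list(counts = C, lag = lag, mode = mode),
            class = "count_matrix")
}

lag_frames <- function(lag, dt) {
  lf <- lag / dt
  if (abs(lf - round(lf)) > 1e-9 || lf < 1) {
    stop("lag must be a positive multiple of dt", call. = FALSE)
  }
  as.integer(round(lf))
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d states, lag = %g, %d transitions (%s)\n",
              nrow(x$counts), x$lag, sum(x$counts), x$mode))
  invisible(x)
}

#' Estimate a transition matrix from transition counts
#'
#' Restricts the counts to the largest strongly connected component of the
#' directed transition graph (dropped states are reported via a warning and
#' the `dropped_states` attribute), optionally symmetrizes the counts as
#' `(C + t(C)) / 2` (enforcing detailed balance of the estimate), and
#' normalizes columns.
#'
#' @param C A [count_transitions()] result.
#' @param symmetrize Symmetrize counts before normalizing (default off).
#' @return A [stochastic_matrix()]; attribute `dropped_states` holds the
#'   0-based indices removed, attribute `kept_states` those retained.
#' @export
estimate_transition_matrix <- function(C, symmetrize = FALSE) {
  stopifnot(inherits(C, "count_matrix"))
  cnt <- C$counts
  ns <- nrow(cnt)
  # edge j -> i for cnt[i, j] > 0; igraph adjacency is [from, to]
  g <- igraph::graph_from_adjacency_matrix((t(cnt) > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- tabulate(comp$membership, comp$no)
  keep_comp <- which.max(sizes)
  keep <- which(comp$membership == keep_comp)
  if (length(keep) == 1 && cnt[keep, keep] == 0) {
    stop("AllDisconnected: no communicating states with counts", call. = FALSE)
  }
  dropped <- setdiff(seq_len(ns), keep)
  if (length(dropped) > 0) {
    warning(sprintf("dropping %d state(s) outside the largest strongly connected component: %s",
                    length(dropped), paste(dropped - 1L, collapse = ", ")))
  }
  cnt <- cnt[keep, keep, drop = FALSE]
  m <- if (symmetrize) (cnt + t(cnt)) / 2 else cnt
  csums <- colSums(m)
  if (any(csums == 0)) stop("AllDisconnected: empty column after restriction",
                            call. = FALSE)
  Tm <- sweep(m, 2, csums, "/")
  out <- stochastic_matrix(Tm, lag = C$lag, tol = 1e-10)
  attr(out, "dropped_states") <- dropped - 1L
  attr(out, "kept_states") <- keep - 1L
  out
}

#' Directly counted time-dependent transition matrices T_MD(t)
#'
#' Estimates the transition matrix independently at each requested lag by
#' sliding-window counting, yielding the approximation-free, time-dependent
#' `T_MD(t)` series. Lag 0 gives the identity. To keep the time averages
#' meaningful, the number of sliding origins available at the longest lag
#' must reach `min_origins`.
#'
#' @param trajs A [trajectory_set()].
#' @param lags Numeric vector of lag times (multiples of `dt`; 0 allowed).
#' @param min_origins Minimum number of counting origins at the longest lag
#'   (default 100 frames).
#' @return List of [stochastic_matrix()] objects, one per lag, on the full
#'   common state alphabet.
#' @export
transition_matrix_series <- function(trajs, lags, min_origins = 100) {
  stopifnot(inherits(trajs, "trajectory_set"))
  ns <- n_states_observed(trajs)
  max_lf <- max(vapply(lags[lags > 0], lag_frames, 0L, dt = trajs$dt), 0L)
  if (max_lf > 0) {
    origins <- sum(pmax(vapply(trajs$trajectories,
                               function(t) length(t$labels), 0L) - max_lf, 0L))
    if (origins < min_origins) {
      stop(sprintf("InsufficientOrigins: %d sliding origins at the longest lag (need >= %d)",
                   origins, min_origins), call. = FALSE)
    }
  }
  lapply(lags, function(lg) {
    if (lg == 0) {
      return(stochastic_matrix(diag(ns), lag = 0))
    }
    C <- count_transitions(trajs, lg, mode = "sliding", n_states = ns)
    csums <- colSums(C$counts)
    if (any(csums == 0)) {
      stop("AllDisconnected: state never observed as origin at this lag",
           call. = FALSE)
    }
    stochastic_matrix(sweep(C$counts, 2, csums, "/"), lag = lg)
  })
}

#' Split trajectories into fixed-length segments
#'
#' Chops every trajectory into consecutive non-overlapping pieces of
#' `segment_frames` frames; a trailing remainder shorter than a segment is
#' dropped and reported through the `dropped_frames` attribute (and a
#' message). Used to emulate building a model from many short runs instead
#' of one long one.
#'
#' @param trajs A [trajectory_set()].
#' @param segment_frames Segment length in frames, >= 2.
#' @return A [trajectory_set()] of the segments, with attribute
#'   `dropped_frames`.
#' @export
split_trajectories <- function(trajs, segment_frames) {
  stopifnot(inherits(trajs, "trajectory_set"))
  if (segment_frames < 2) stop("segment_frames must be >= 2", call. = FALSE)
  segs <- list()
  dropped <- 0L
  for (tr in trajs$trajectories) {
    n <- length(tr$labels)
    k <- n %/% segment_frames
    dropped <- dropped + (n - k * segment_frames)
    if (k > 0) {
      for (s in seq_len(k)) {
        idx <- ((s - 1) * segment_frames + 1):(s * segment_frames)
        segs[[length(segs) + 1]] <- discrete_trajectory(tr$labels[idx],
                                                        dt = tr$dt)
      }
    }
  }
  if (length(segs) == 0) {
    # degenerate: nothing fits; an empty set is returned (with a report)
    # rather than erroring, so callers can detect it
    message(sprintf("no segment fits: all %d frames dropped", dropped))
    out <- structure(list(trajectories = list(), dt = trajs$dt,
                          state_map = trajs$state_map),
                     class = "trajectory_set")
    attr(out, "dropped_frames") <- dropped
    return(out)
  }
  if (dropped > 0) message(sprintf("dropped %d trailing frame(s)", dropped))
  out <- trajectory_set(segs, state_map = trajs$state_map)
  attr(out, "dropped_frames") <- dropped
  out
}
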