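#' Uniformly sampled multivariate activation trajectory
#'
#' Container for node activation time series: a T x N matrix of activation
#' levels in `[0, 1]` sampled on a uniform time grid. For resting-state fMRI
#' the sampling interval `dt` is the repetition time (about 3 s in a typical
#' acquisition).
#'
#' @param states T x N numeric matrix, one row per time point.
#' @param dt Sampling interval in seconds (> 0). Ignored when `times` is
#'   given.
#' @param times Optional explicit time grid of length T; must be uniform and
#'   strictly increasing.
#' @param labels Optional node labels (defaults to column names or `n1..nN`).
#' @param t0 Time of the first sample (seconds) when `times` is not given.
#' @return An object of class `egnb_trajectory`: a list with `times`,
#'   `states`, `dt`.
#' @export
trajectory <- function(states, dt = NULL, times = NULL, labels = NULL, t0 = 0) {
  if (!is.matrix(states)) states <- as.matrix(states)
  if (!is.numeric(states) || any(!is.finite(states))) {
    stop("trajectory states must be finite numbers", call. = FALSE)
  }
  if (any(states < 0 | states > 1)) {
    stop("trajectory states must lie in [0, 1]", call. = FALSE)
  }
  T_ <- nrow(states)
  if (T_ < 1L) stop("trajectory needs at least one sample", call. = FALSE)
  if (is.null(times)) {
    if (is.null(dt)) stop("supply either dt or times", call. = FALSE)
    stopifnot(is.numeric(dt), length(dt) == 1L, dt > 0)
    times <- t0 + dt * (seq_len(T_) - 1)
  } else {
    if (length(times) != T_) {
      stop("length of times must match number of state rows", call. = FALSE)
    }
    dt <- check_uniform_grid(times)
  }
  if (is.null(labels)) {
    labels <- colnames(states)
    if (is.null(labels)) labels <- paste0("n", seq_len(ncol(states)))
  }
  if (length(labels) != ncol(states)) {
    stop("need one label per node", call. = FALSE)
  }
  colnames(states) <- labels
  structure(list(times = as.numeric(times), states = states, dt = dt),
            class = "egnb_trajectory")
}

check_uniform_grid <- function(times, tol = 1e-8) {
  if (length(times) < 2L) return(NA_real_)
  d <- diff(times)
  if (any(d <= 0)) stop("time grid must be strictly increasing", call. = FALSE)
  dt <- d[1]
  if (any(abs(d - dt) > tol * max(dt, 1))) {
    stop("time grid must be uniform", call. = FALSE)
  }
  dt
}

#' @export
print.egnb_trajectory <- function(x, ...) {
  cat(sprintf("<egnb_trajectory> %d samples x %d nodes, dt = %g s, t in [%g, %g]\n",
              nrow(x$states), ncol(x$states), x$dt,
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

#' @export
as.matrix.egnb_trajectory <- function(x, ...) x$states

n_samples <- function(traj) nrow(traj$states)
n_nodes <- function(traj) ncol(traj$states)

#' Restrict a trajectory to a subset of nodes
#'
#' @param traj An [trajectory()] object.
#' @param nodes Character vector of node labels or integer column indices.
#' @return The sub-trajectory on the selected nodes.
#' @export
subset_nodes <- function(traj, nodes) {
  stopifnot(inherits(traj, "egnb_trajectory"))
  states <- traj$states[, nodes, drop = FALSE]
  trajectory(states, times = traj$times)
}
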