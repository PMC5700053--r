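#' Integrator options for the replicator dynamics
#'
#' @param method `"rk4_fixed"` (classical Runge-Kutta with a fixed internal
#'   step, the default) or `"adaptive"` (lsoda via \pkg{deSolve}).
#' @param step Internal step in seconds for the fixed-step integrator;
#'   `NULL` means one tenth of the output sampling interval.
#' @param abs_tol,rel_tol Absolute/relative tolerances for the adaptive
#'   integrator.
#' @param state_clip_eps Safety margin: a state component that escapes
#'   `[0, 1]` by roundoff after an output step is pulled back to
#'   `[eps, 1 - eps]`. Components exactly on the boundary are legitimate
#'   equilibria and are left untouched.
#' @return An object of class `solver_options`.
#' @export
solver_options <- function(method = c("rk4_fixed", "adaptive"), step = NULL,
                           abs_tol = 1e-8, rel_tol = 1e-8,
                           state_clip_eps = 1e-9) {
  method <- match.arg(method)
  if (!is.null(step)) stopifnot(is.numeric(step), length(step) == 1L, step > 0)
  stopifnot(abs_tol > 0, rel_tol > 0,
            state_clip_eps >= 0, state_clip_eps < 0.5)
  structure(list(method = method, step = step, abs_tol = abs_tol,
                 rel_tol = rel_tol, state_clip_eps = state_clip_eps),
            class = "solver_options")
}

check_propensity_matrices <- function(conn, propensities) {
  n <- nrow(conn)
  a <- propensities$alpha
  i <- propensities$iota
  if (!is.matrix(a) || !is.matrix(i) || !all(dim(a) == n) || !all(dim(i) == n)) {
    stop("propensities$alpha and $iota must be N x N matrices", call. = FALSE)
  }
  if (any(a * i < 0)) {
    stop("per-edge propensities must not have mixed signs", call. = FALSE)
  }
  invisible(TRUE)
}

# Net payoff drive sum_w a_{v,w} dp_{v,w} for a K x N matrix of states.
# Restricted mode (propensities NULL): alpha = iota = sign(a'), so the drive
# is linear in the signed matrix, X2 %*% t(conn) with X2 = 2X - 1.
net_payoff_drive <- function(X, conn, propensities = NULL) {
  if (is.null(propensities)) {
    (2 * X - 1) %*% t(as_conn_matrix(conn))
  } else {
    W <- coupling_weights(conn)
    a <- propensities$alpha
    i <- propensities$iota
    X %*% t(W * (a + i)) - rep(rowSums(W * i), each = nrow(X))
  }
}

#' Right-hand side of the replicator equation on a graph
#'
#' Each region's activation level evolves as
#' `dx_v/dt = x_v (1 - x_v) * sum_w a_{v,w} dp_{v,w}`,
#' where `a_{v,w} >= 0` are coupling weights and `dp_{v,w}` is the
#' activation-minus-inactivation payoff difference of the pairwise game. In
#' the restricted mode used for identification the propensities equal the
#' sign of the signed connectivity entry, and the drive simplifies to
#' `sum_w a'_{v,w} (2 x_w - 1)`, linear in the signed matrix.
#'
#' @param state Numeric vector of N activation levels in `[0, 1]`.
#' @param conn A [signed_connectivity()] matrix (or plain square matrix).
#' @param propensities Optional general mode: a list with N x N matrices
#'   `alpha` and `iota` of per-edge propensities (equal sign per edge);
#'   `conn` then contributes only its weights `abs(conn)`.
#' @return Numeric vector of N time derivatives.
#' @export
replicator_rhs <- function(state, conn, propensities = NULL) {
  n <- nrow(conn)
  if (length(state) != n) {
    stop("state length must match connectivity dimension", call. = FALSE)
  }
  if (any(state < 0 | state > 1)) {
    stop("state components must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(propensities)) check_propensity_matrices(conn, propensities)
  drive <- net_payoff_drive(matrix(state, nrow = 1L), conn, propensities)
  as.numeric(state * (1 - state) * drive)
}

# Pull components that escaped [0,1] back inside; exact boundary values are
# equilibria and must be preserved.
clip_escaped <- function(x, eps) {
  x[x < 0] <- eps
  x[x > 1] <- 1 - eps
  x
}

rk4_path <- function(x0, times, conn, propensities, opts) {
  dt <- times[2] - times[1]
  h0 <- if (is.null(opts$step)) dt / 10 else opts$step
  nsub <- max(1L, as.integer(round(dt / h0)))
  h <- dt / nsub
  T_ <- length(times)
  n <- length(x0)
  out <- matrix(NA_real_, T_, n)
  out[1, ] <- x0
  f <- function(x) as.numeric(x * (1 - x) * net_payoff_drive(matrix(x, nrow = 1L),
                                                             conn, propensities))
  x <- x0
  for (k in seq_len(T_ - 1L)) {
    for (s in seq_len(nsub)) {
      # the RHS is a polynomial, so intermediate stages may probe slightly
      # outside [0,1] without harm; only committed states are clipped
      k1 <- f(x)
      k2 <- f(x + h / 2 * k1)
      k3 <- f(x + h / 2 * k2)
      k4 <- f(x + h * k3)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    x <- clip_escaped(x, opts$state_clip_eps)
    out[k + 1L, ] <- x
  }
  out
}

adaptive_path <- function(x0, times, conn, propensities, opts) {
  rhs_desolve <- function(t, y, parms) {
    list(as.numeric(y * (1 - y) * net_payoff_drive(matrix(y, nrow = 1L),
                                                   conn, propensities)))
  }
  sol <- deSolve::ode(y = x0, times = times, func = rhs_desolve, parms = NULL,
                      method = "lsoda", atol = opts$abs_tol,
                      rtol = opts$rel_tol)
  out <- unname(as.matrix(sol[, -1, drop = FALSE]))
  t(apply(out, 1L, clip_escaped, eps = opts$state_clip_eps))
}

#' Integrate the replicator dynamics forward in time
#'
#' Solves the replicator equation on the graph from initial condition `x0`
#' and returns the solution sampled on a uniform grid. Deterministic given
#' `(conn, x0, opts)`.
#'
#' @param conn A [signed_connectivity()] matrix.
#' @param x0 Initial activation levels, length N, in `[0, 1]`.
#' @param times Uniform output time grid; alternatively give `n_samples`
#'   and `dt`.
#' @param n_samples,dt Number of output samples and sampling interval in
#'   seconds, used when `times` is `NULL`.
#' @param opts A [solver_options()] object.
#' @param propensities Optional general-mode per-edge propensities, see
#'   [replicator_rhs()].
#' @return An [trajectory()] object on the requested grid.
#' @export
#' @examples
#' conn <- signed_connectivity(matrix(c(0, 1, 1, 0), 2, 2))
#' simulate_egnb(conn, c(0.3, 0.8), n_samples = 50, dt = 1)
simulate_egnb <- function(conn, x0, times = NULL, n_samples = NULL, dt = NULL,
                          opts = solver_options(), propensities = NULL) {
  n <- nrow(conn)
  if (length(x0) != n) stop("x0 length must match network size", call. = FALSE)
  if (any(x0 < 0 | x0 > 1)) stop("x0 must lie in [0, 1]", call. = FALSE)
  if (!is.null(propensities)) check_propensity_matrices(conn, propensities)
  if (is.null(times)) {
    if (is.null(n_samples) || is.null(dt)) {
      stop("supply either times or (n_samples, dt)", call. = FALSE)
    }
    times <- dt * (seq_len(n_samples) - 1)
  } else {
    check_uniform_grid(times)
  }
  if (length(times) < 2L) {
    return(trajectory(matrix(x0, nrow = 1L,
                             dimnames = list(NULL, node_labels(conn))),
                      dt = 1, t0 = times[1]))
  }
  states <- switch(opts$method,
    rk4_fixed = rk4_path(x0, times, conn, propensities, opts),
    adaptive  = adaptive_path(x0, times, conn, propensities, opts))
  colnames(states) <- node_labels(conn)
  trajectory(states, times = times)
}

#' Net payoff drive along a trajectory
#'
#' For each node and time point, the weighted sum of pairwise payoff
#' differences `sum_w a_{v,w} dp_{v,w}` evaluated on the trajectory states.
#' In the interior of the state space this drive carries the sign of the
#' node's time derivative, so its zero crossings anticipate turning points
#' of the activation signal.
#'
#' @param traj An [trajectory()] object.
#' @param conn A [signed_connectivity()] matrix with matching dimension.
#' @param propensities Optional general-mode propensities.
#' @return T x N numeric matrix of net payoff drives.
#' @export
payoff_time_series <- function(traj, conn, propensities = NULL) {
  stopifnot(inherits(traj, "egnb_trajectory"))
  if (ncol(traj$states) != nrow(conn)) {
    stop("trajectory and connectivity dimensions do not match", call. = FALSE)
  }
  if (!is.null(propensities)) check_propensity_matrices(conn, propensities)
  drive <- net_payoff_drive(traj$states, conn, propensities)
  dimnames(drive) <- list(NULL, node_labels(conn))
  drive
}
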