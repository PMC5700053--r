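#' Map raw BOLD series onto the activation interval
#'
#' The model states are activation levels in `[0, 1]`, while BOLD signals
#' are in arbitrary scanner units. Each node's series is mapped affinely
#' (min-max) onto `[delta, 1 - delta]`; the margin keeps `x (1 - x)` bounded
#' away from zero so every sample carries information for the estimator.
#' The per-node parameters returned are sufficient to invert the map.
#'
#' @param raw T x N numeric matrix of raw signals (rows = time points).
#' @param delta Margin in `(0, 0.25]`; default 0.05.
#' @param dt Sampling interval in seconds for the returned trajectory.
#' @param labels Optional node labels.
#' @return A list with `trajectory` (an [trajectory()]) and `scaling`
#'   (class `bold_scaling`: per-node `gain` and `offset` with
#'   `scaled = gain * raw + offset`).
#' @export
scale_bold <- function(raw, delta = 0.05, dt = 1, labels = NULL) {
  if (!is.matrix(raw)) raw <- as.matrix(raw)
  stopifnot(is.numeric(raw), nrow(raw) >= 2L)
  if (!(delta > 0 && delta <= 0.25)) {
    stop("delta must lie in (0, 0.25]", call. = FALSE)
  }
  if (is.null(labels)) {
    labels <- colnames(raw)
    if (is.null(labels)) labels <- paste0("n", seq_len(ncol(raw)))
  }
  lo <- apply(raw, 2L, min)
  hi <- apply(raw, 2L, max)
  flat <- which(hi - lo <= 0)
  if (length(flat)) {
    stop("constant series cannot be scaled: node(s) ",
         paste(labels[flat], collapse = ", "), call. = FALSE)
  }
  gain <- (1 - 2 * delta) / (hi - lo)
  offset <- delta - gain * lo
  scaled <- sweep(sweep(raw, 2L, gain, `*`), 2L, offset, `+`)
  # guard roundoff at the range endpoints
  scaled <- pmin(pmax(scaled, delta), 1 - delta)
  scaling <- structure(list(gain = gain, offset = offset, delta = delta,
                            labels = labels),
                       class = "bold_scaling")
  list(trajectory = trajectory(scaled, dt = dt, labels = labels),
       scaling = scaling)
}

#' Invert the BOLD scaling map
#'
#' @param scaled T x N matrix or [trajectory()] of scaled states.
#' @param scaling The `bold_scaling` object returned by [scale_bold()].
#' @return Matrix of raw-unit signals.
#' @export
unscale_bold <- function(scaled, scaling) {
  stopifnot(inherits(scaling, "bold_scaling"))
  m <- if (inherits(scaled, "egnb_trajectory")) scaled$states else as.matrix(scaled)
  sweep(sweep(m, 2L, scaling$offset, `-`), 2L, scaling$gain, `/`)
}

#' Discretized linear regression system for connectivity estimation
#'
#' Discretizing the restricted-mode replicator equation by forward Euler at
#' the sampling interval gives, for node `v` and sample `k`,
#' `(x_v[k+1] - x_v[k]) / dt = x_v[k] (1 - x_v[k]) * sum_w theta_{v,w} (2 x_w[k] - 1)`,
#' which is linear in the signed connectivity entries `theta`. The full
#' system stacks one block of `T - 1` rows per node; blocks are decoupled
#' (exact block-diagonal sparsity), so they are stored per node. The least
#' squares functional `F(theta) = ||Y - U theta||` is convex with a unique
#' minimiser whenever the design has full rank.
#'
#' @param traj An [trajectory()] with at least 2 samples and states strictly
#'   inside `(0, 1)`.
#' @param scheme `"euler"` (forward difference, default) or `"central"`
#'   (two-point central difference, regressors at the interior samples).
#' @return An object of class `regression_system`: list with `blocks` (per
#'   node: design matrix `X` of size K x N and response `y` of length K),
#'   `dt`, `labels`, `scheme`.
#' @export
build_regression <- function(traj, scheme = c("euler", "central")) {
  stopifnot(inherits(traj, "egnb_trajectory"))
  scheme <- match.arg(scheme)
  X <- traj$states
  T_ <- nrow(X)
  if (T_ < 2L) stop("need at least 2 samples", call. = FALSE)
  bad <- which(apply(X <= 0 | X >= 1, 2L, any))
  if (length(bad)) {
    stop("states on the boundary make the regressor x(1-x) vanish; ",
         "scale the data first (node(s) ",
         paste(colnames(X)[bad], collapse = ", "), ")", call. = FALSE)
  }
  dt <- traj$dt
  labels <- colnames(X)
  n <- ncol(X)
  if (scheme == "euler") {
    idx <- seq_len(T_ - 1L)                      # regressors at sample k
    base <- 2 * X[idx, , drop = FALSE] - 1       # (2 x_w[k] - 1)
    resp <- (X[idx + 1L, , drop = FALSE] - X[idx, , drop = FALSE]) / dt
    gmat <- X[idx, , drop = FALSE] * (1 - X[idx, , drop = FALSE])
  } else {
    if (T_ < 3L) stop("central scheme needs at least 3 samples", call. = FALSE)
    idx <- seq(2L, T_ - 1L)
    base <- 2 * X[idx, , drop = FALSE] - 1
    resp <- (X[idx + 1L, , drop = FALSE] - X[idx - 1L, , drop = FALSE]) / (2 * dt)
    gmat <- X[idx, , drop = FALSE] * (1 - X[idx, , drop = FALSE])
  }
  blocks <- lapply(seq_len(n), function(v) {
    list(X = unname(base * gmat[, v]), y = unname(resp[, v]))
  })
  names(blocks) <- labels
  structure(list(blocks = blocks, dt = dt, labels = labels, scheme = scheme),
            class = "regression_system")
}

#' @export
print.regression_system <- function(x, ...) {
  k <- length(x$blocks[[1]]$y)
  n <- length(x$labels)
  cat(sprintf("<regression_system> %d nodes, %d rows/block (%d x %d stacked), scheme = %s\n",
              n, k, n * k, n * n, x$scheme))
  invisible(x)
}

#' Assemble the stacked design matrix and response of a regression system
#'
#' Builds the dense `N(T-1) x N^2` design with its block-diagonal sparsity
#' pattern and the stacked response vector. Intended for inspection and for
#' small problems; estimation itself solves the decoupled per-node blocks.
#'
#' @param rs A `regression_system` from [build_regression()].
#' @return List with `U` (dense matrix) and `Y` (vector); parameter column
#'   `(v - 1) * N + w` corresponds to entry `(v, w)` of the signed matrix.
#' @export
assemble_regression <- function(rs) {
  stopifnot(inherits(rs, "regression_system"))
  n <- length(rs$labels)
  k <- length(rs$blocks[[1]]$y)
  U <- matrix(0, n * k, n * n)
  Y <- numeric(n * k)
  for (v in seq_len(n)) {
    rows <- (v - 1L) * k + seq_len(k)
    cols <- (v - 1L) * n + seq_len(n)
    U[rows, cols] <- rs$blocks[[v]]$X
    Y[rows] <- rs$blocks[[v]]$y
  }
  list(U = U, Y = Y)
}

solve_block <- function(X, y, ridge, label) {
  n <- ncol(X)
  if (ridge == 0) {
    qrx <- qr(X)
    if (qrx$rank < n) {
      stop("rank-deficient design for node ", label,
           " (rank ", qrx$rank, " < ", n, "); use ridge > 0 or a longer, ",
           "more informative series", call. = FALSE)
    }
    qr.coef(qrx, y)
  } else {
    solve(crossprod(X) + diag(ridge, n), crossprod(X, y))[, 1L]
  }
}

#' Estimate the signed connectivity matrix by linear least squares
#'
#' Solves the convex problem `min_theta ||Y - U theta||` of the discretized
#' model (see [build_regression()]) through the normal equations /
#' QR factorisation, independently per node block, and reshapes the unique
#' minimiser into the signed connectivity matrix. With `ridge = 0` this is
#' the plain least squares solution `(U'U)^{-1} U'Y`; a positive ridge adds
#' Tikhonov regularisation for rank-deficient designs.
#'
#' @param traj An [trajectory()] with states strictly inside `(0, 1)`.
#' @param ridge Non-negative regularisation weight (default 0).
#' @param scheme Discretization scheme, see [build_regression()].
#' @return The estimated [signed_connectivity()] matrix.
#' @export
#' @examples
#' truth <- signed_connectivity(matrix(c(0, .1, -.1, 0), 2, 2, byrow = TRUE))
#' spec <- synthetic_spec(cluster_sizes = 2, noise_sd = 0, n_samples = 120, seed = 1)
#' traj <- generate_trajectory(truth, spec)
#' estimate_connectivity(traj)
estimate_connectivity <- function(traj, ridge = 0, scheme = c("euler", "central")) {
  stopifnot(is.numeric(ridge), length(ridge) == 1L, ridge >= 0)
  rs <- build_regression(traj, scheme = match.arg(scheme))
  n <- length(rs$labels)
  A <- matrix(NA_real_, n, n)
  for (v in seq_len(n)) {
    A[v, ] <- solve_block(rs$blocks[[v]]$X, rs$blocks[[v]]$y, ridge,
                          rs$labels[v])
  }
  signed_connectivity(A, labels = rs$labels)
}

max_lagged_cor <- function(obs, sim, max_lag = 10L) {
  T_ <- length(obs)
  best <- NA_real_
  for (lag in -max_lag:max_lag) {
    if (lag >= 0) {
      o <- obs[seq_len(T_ - lag)]
      s <- sim[seq_len(T_ - lag) + lag]
    } else {
      o <- obs[seq_len(T_ + lag) - lag]
      s <- sim[seq_len(T_ + lag)]
    }
    if (length(o) < 3L) next
    if (stats::sd(o) == 0 || stats::sd(s) == 0) next
    r <- stats::cor(o, s)
    if (is.na(best) || r > best) best <- r
  }
  best
}

#' Goodness of fit of a connectivity matrix against observed series
#'
#' Simulates the model from the first observed sample over the observed
#' grid and compares simulation with data: root-mean-square error per node
#' and overall, and the maximum normalised cross-correlation per node over
#' lags within +/- `max_lag` samples.
#'
#' @param traj Observed [trajectory()].
#' @param conn A [signed_connectivity()] matrix.
#' @param opts [solver_options()] for the forward simulation.
#' @param max_lag Lag window (samples) for the cross-correlation search.
#' @return List with `rmse_per_node`, `rmse_overall`,
#'   `max_crosscorr_per_node` (NA where either series is constant), and the
#'   simulated trajectory as `simulated`.
#' @export
fit_quality <- function(traj, conn, opts = solver_options(), max_lag = 10L) {
  stopifnot(inherits(traj, "egnb_trajectory"))
  if (ncol(traj$states) != nrow(conn)) {
    stop("trajectory and connectivity dimensions do not match", call. = FALSE)
  }
  sim <- simulate_egnb(conn, x0 = traj$states[1L, ], times = traj$times,
                       opts = opts)
  err <- traj$states - sim$states
  rmse_per_node <- sqrt(colMeans(err^2))
  ccs <- vapply(seq_len(ncol(err)), function(v) {
    max_lagged_cor(traj$states[, v], sim$states[, v], max_lag = max_lag)
  }, numeric(1))
  names(ccs) <- colnames(traj$states)
  list(rmse_per_node = rmse_per_node,
       rmse_overall = sqrt(mean(err^2)),
       max_crosscorr_per_node = ccs,
       simulated = sim)
}
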