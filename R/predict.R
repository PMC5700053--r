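#' Iterate the forward-Euler map of the restricted-mode model
#'
#' The discrete-time system used by the estimator:
#' `x[k+1] = x[k] + dt * x[k] (1 - x[k]) * (conn %*% (2 x[k] - 1))`,
#' clipped into `[eps, 1 - eps]` on escape. Predicting with the same
#' discretization under which the matrix was estimated makes noiseless
#' round trips exact.
#'
#' @keywords internal
euler_path <- function(conn, x0, n_steps, dt, eps = 1e-9, clamp_full = FALSE) {
  n <- length(x0)
  out <- matrix(NA_real_, n_steps + 1L, n)
  out[1L, ] <- x0
  A <- as_conn_matrix(conn)
  x <- x0
  for (k in seq_len(n_steps)) {
    xn <- x + dt * x * (1 - x) * as.numeric(A %*% (2 * x - 1))
    if (clamp_full) {
      # keep MOVING states off the exact boundary: rounding can pin a
      # saturating state at exactly 0 or 1 (where the regressor x(1-x)
      # vanishes) even though the exact map never reaches it; states whose
      # update is exactly zero are genuine fixed points and stay put
      moved <- xn != x
      xn[moved] <- pmin(pmax(xn[moved], eps), 1 - eps)
    } else {
      xn <- clip_escaped(xn, eps)
    }
    x <- xn
    out[k + 1L, ] <- x
  }
  out
}

holdout_errors <- function(pred, obs) {
  stopifnot(all(dim(pred) == dim(obs)))
  per_h <- rowMeans(abs(pred - obs))
  list(per_horizon_error = per_h,
       summary = list(mean_error = mean(per_h),
                      sd_error = stats::sd(per_h),
                      rmse = sqrt(mean((pred - obs)^2))))
}

new_prediction_report <- function(model, n_train, predicted, obs_times, errs) {
  structure(c(list(model = model, n_train = n_train,
                   horizon = length(errs$per_horizon_error),
                   predicted = predicted),
              errs),
            class = "prediction_report")
}

#' @export
print.prediction_report <- function(x, ...) {
  cat(sprintf("<prediction_report> %s model, trained on %d samples, horizon %d\n",
              x$model, x$n_train, x$horizon))
  cat(sprintf("  mean abs error = %.4g (sd %.4g), rmse = %.4g\n",
              x$summary$mean_error, x$summary$sd_error, x$summary$rmse))
  invisible(x)
}

#' Estimate on an initial window and predict the held-out remainder
#'
#' Estimates the signed connectivity matrix on the first `n_train` samples,
#' then runs the model forward from the last training state across the
#' held-out grid. By default the forward run iterates the same forward-Euler
#' discretization used by the estimator (`simulator = "euler"`); the
#' continuous-time integrator is available with `simulator = "ode"`. The
#' per-horizon error is the mean over nodes of the absolute deviation at
#' each held-out step, with an RMSE summary alongside.
#'
#' @param traj Observed [trajectory()], states strictly inside `(0, 1)`.
#' @param n_train Number of leading samples used for estimation
#'   (`2 <= n_train < T`). The default 90 mirrors a typical fMRI protocol
#'   where the first 90 volumes train the model.
#' @param ridge,scheme Passed to [estimate_connectivity()].
#' @param simulator `"euler"` (discrete map, default) or `"ode"`
#'   (continuous integration via [simulate_egnb()]).
#' @param opts [solver_options()] used when `simulator = "ode"`.
#' @return A `prediction_report`: list with `model`, `n_train`, `horizon`,
#'   `predicted` (trajectory on the held-out grid), `per_horizon_error`,
#'   `summary` (`mean_error`, `sd_error`, `rmse`), and the estimated matrix
#'   as attribute `"conn"`.
#' @export
predict_egnb <- function(traj, n_train = 90L, ridge = 0,
                         scheme = c("euler", "central"),
                         simulator = c("euler", "ode"),
                         opts = solver_options()) {
  stopifnot(inherits(traj, "egnb_trajectory"))
  simulator <- match.arg(simulator)
  T_ <- n_samples(traj)
  if (n_train < 2L || n_train >= T_) {
    stop("n_train must satisfy 2 <= n_train < T", call. = FALSE)
  }
  train <- trajectory(traj$states[seq_len(n_train), , drop = FALSE],
                      times = traj$times[seq_len(n_train)])
  conn <- estimate_connectivity(train, ridge = ridge, scheme = scheme)
  x_start <- traj$states[n_train, ]
  h <- T_ - n_train
  if (simulator == "euler") {
    path <- euler_path(conn, x_start, n_steps = h, dt = traj$dt)
  } else {
    sim <- simulate_egnb(conn, x_start, times = traj$times[n_train:T_],
                         opts = opts)
    path <- sim$states
  }
  pred <- path[-1L, , drop = FALSE]     # held-out steps only
  obs <- traj$states[(n_train + 1L):T_, , drop = FALSE]
  errs <- holdout_errors(pred, obs)
  colnames(pred) <- colnames(traj$states)
  rep <- new_prediction_report("egnb", n_train,
                               trajectory(pred, times = traj$times[(n_train + 1L):T_]),
                               traj$times, errs)
  attr(rep, "conn") <- conn
  rep
}

#' Prediction error as a function of the training-window length
#'
#' Runs [predict_egnb()] for each training fraction and tabulates the
#' held-out error summaries, tracing how predictive power grows with the
#' amount of data used for estimation.
#'
#' @param traj Observed [trajectory()].
#' @param fractions Training fractions in `(0, 1)`; each must give a window
#'   of at least N + 1 samples.
#' @param ... Passed to [predict_egnb()].
#' @return A data.frame with columns `fraction`, `n_train`, `mean_error`,
#'   `sd_error`, `rmse`.
#' @export
error_vs_window <- function(traj, fractions, ...) {
  stopifnot(inherits(traj, "egnb_trajectory"))
  if (length(fractions) == 0L) {
    return(data.frame(fraction = numeric(0), n_train = integer(0),
                      mean_error = numeric(0), sd_error = numeric(0),
                      rmse = numeric(0)))
  }
  stopifnot(all(fractions > 0 & fractions < 1))
  T_ <- n_samples(traj)
  n <- n_nodes(traj)
  rows <- lapply(fractions, function(f) {
    n_train <- floor(f * T_)
    if (n_train < n + 1L) {
      stop(sprintf("fraction %.3g gives %d training samples; need at least N + 1 = %d",
                   f, n_train, n + 1L), call. = FALSE)
    }
    rep <- predict_egnb(traj, n_train = n_train, ...)
    data.frame(fraction = f, n_train = n_train,
               mean_error = rep$summary$mean_error,
               sd_error = rep$summary$sd_error,
               rmse = rep$summary$rmse)
  })
  do.call(rbind, rows)
}

#' Fit quality as a function of network size
#'
#' For each requested size, draws random node subsets (seeded), estimates
#' the connectivity on the sub-network's series and evaluates
#' [fit_quality()]; reports the mean overall RMSE and the mean of per-node
#' maximum cross-correlations. Nodes omitted from a subset keep influencing
#' the retained ones in the data but are invisible to the estimator, so
#' small subsets carry an omitted-node bias.
#'
#' @param traj Observed [trajectory()].
#' @param sizes Integer vector of subset sizes (each `>= 2`, `<= N`).
#' @param seed Integer seed for the subset draws.
#' @param n_draws Subsets drawn per size (errors are averaged).
#' @param ridge,scheme Passed to [estimate_connectivity()].
#' @param opts [solver_options()] for [fit_quality()].
#' @return A data.frame with columns `n_nodes`, `mean_fit_error`,
#'   `mean_max_crosscorr`.
#' @export
error_vs_network_size <- function(traj, sizes, seed = 1L, n_draws = 1L,
                                  ridge = 0, scheme = c("euler", "central"),
                                  opts = solver_options()) {
  stopifnot(inherits(traj, "egnb_trajectory"))
  scheme <- match.arg(scheme)
  if (length(sizes) == 0L) {
    return(data.frame(n_nodes = integer(0), mean_fit_error = numeric(0),
                      mean_max_crosscorr = numeric(0)))
  }
  n <- n_nodes(traj)
  stopifnot(all(sizes >= 2L), all(sizes <= n))
  rows <- with_seed(seed, lapply(sizes, function(s) {
    errs <- numeric(n_draws)
    ccs <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      keep <- if (s == n) seq_len(n) else sort(sample.int(n, s))
      sub <- subset_nodes(traj, keep)
      conn <- estimate_connectivity(sub, ridge = ridge, scheme = scheme)
      fq <- fit_quality(sub, conn, opts = opts)
      errs[d] <- fq$rmse_overall
      ccs[d] <- mean(fq$max_crosscorr_per_node, na.rm = TRUE)
    }
    data.frame(n_nodes = s, mean_fit_error = mean(errs),
               mean_max_crosscorr = mean(ccs))
  }))
  do.call(rbind, rows)
}

#' Affine linear (AR(1)) baseline prediction
#'
#' Fits the discrete linear system `x[k+1] = M x[k] + c` by least squares
#' on the training window and iterates it over the held-out window. The fit
#' is parameterised on the one-step change (`M - I` and `c`), so a positive
#' ridge shrinks towards the random-walk model `x[k+1] = x[k]` rather than
#' towards zero; with `ridge = 0` this is the plain least squares solution.
#' The error functional is identical to [predict_egnb()]'s, so the two
#' reports are directly comparable.
#'
#' @param traj Observed [trajectory()].
#' @param n_train Training window length (`N + 2 <= n_train < T` for a
#'   full-rank fit).
#' @param ridge Optional Tikhonov weight for the linear fit.
#' @return A `prediction_report` with `model = "linear"`; the fitted `M`
#'   and `c` are attached as attribute `"coef"`.
#' @export
fit_linear_baseline <- function(traj, n_train = 90L, ridge = 0) {
  stopifnot(inherits(traj, "egnb_trajectory"))
  T_ <- n_samples(traj)
  n <- n_nodes(traj)
  if (n_train < 2L || n_train >= T_) {
    stop("n_train must satisfy 2 <= n_train < T", call. = FALSE)
  }
  X0 <- cbind(traj$states[seq_len(n_train - 1L), , drop = FALSE], 1)
  D <- traj$states[2:n_train, , drop = FALSE] -
    traj$states[seq_len(n_train - 1L), , drop = FALSE]
  if (ridge == 0) {
    qrx <- qr(X0)
    if (qrx$rank < n + 1L) {
      stop("rank-deficient linear fit; use ridge > 0 or a longer window",
           call. = FALSE)
    }
    B <- qr.coef(qrx, D)
  } else {
    B <- solve(crossprod(X0) + diag(ridge, n + 1L), crossprod(X0, D))
  }
  M <- diag(n) + t(B[seq_len(n), , drop = FALSE])
  cc <- as.numeric(B[n + 1L, ])
  x <- traj$states[n_train, ]
  h <- T_ - n_train
  pred <- matrix(NA_real_, h, n)
  for (k in seq_len(h)) {
    x <- as.numeric(M %*% x + cc)
    pred[k, ] <- x
  }
  obs <- traj$states[(n_train + 1L):T_, , drop = FALSE]
  # a linear iterate can leave the state space; clamp to valid activations
  # before scoring so both models are judged on admissible predictions
  pred <- pmin(pmax(pred, 0), 1)
  errs <- holdout_errors(pred, obs)
  colnames(pred) <- colnames(traj$states)
  pred_traj <- trajectory(pred, times = traj$times[(n_train + 1L):T_])
  rep <- new_prediction_report("linear", n_train, pred_traj, traj$times, errs)
  attr(rep, "coef") <- list(M = M, c = cc)
  rep
}
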