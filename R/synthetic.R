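# Evaluate expr with a local, restored RNG state so generators are
# bit-reproducible without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specification of a synthetic modular ground truth and its trajectories
#'
#' Describes the study conditions for synthetic validation data: a modular
#' network of emulative clusters (positive couplings within a cluster)
#' that oppose each other (negative couplings between clusters), echoing
#' the within-network synchrony and between-network anti-correlation of
#' resting-state fMRI, plus an fMRI-like sampling regime of one sample
#' every 3 seconds for 180 samples (9 minutes of acquisition).
#'
#' Coupling magnitudes default to `[0.02, 0.08]`: in the replicator model
#' only the product of coupling strength and sampling interval matters for
#' the discrete dynamics, and at a 3-second repetition time these weights
#' keep per-step activation updates to a few percent of the dynamic range,
#' matching the slow fluctuations seen in BOLD recordings. Observation
#' noise is additive Gaussian on the states (measurement noise), not
#' process noise.
#'
#' @param cluster_sizes Integer vector of cluster sizes (N = sum).
#' @param weight_range Length-2 positive range for coupling magnitudes.
#' @param density_within,density_between Edge probabilities within/between
#'   clusters.
#' @param self_loop_prob Probability of a (positive) self loop per node.
#' @param within_sign,between_sign Attitude signs (+1 emulative within,
#'   -1 non-emulative between; fixed signs of the motif).
#' @param noise_sd Standard deviation of the additive observation noise.
#' @param dt Sampling interval in seconds.
#' @param n_samples Number of time samples.
#' @param seed Integer seed making every draw reproducible.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(cluster_sizes = c(5L, 5L),
                           weight_range = c(0.02, 0.08),
                           density_within = 0.9, density_between = 0.4,
                           self_loop_prob = 0.25,
                           within_sign = 1, between_sign = -1,
                           noise_sd = 0.01, dt = 3, n_samples = 180L,
                           seed = 1L) {
  stopifnot(length(cluster_sizes) >= 1L, all(cluster_sizes >= 1L),
            length(weight_range) == 2L, all(weight_range > 0),
            weight_range[1] <= weight_range[2],
            density_within >= 0, density_within <= 1,
            density_between >= 0, density_between <= 1,
            self_loop_prob >= 0, self_loop_prob <= 1,
            within_sign > 0, between_sign < 0,
            noise_sd >= 0, dt > 0, n_samples >= 2L)
  structure(list(cluster_sizes = as.integer(cluster_sizes),
                 weight_range = weight_range,
                 density_within = density_within,
                 density_between = density_between,
                 self_loop_prob = self_loop_prob,
                 within_sign = within_sign, between_sign = between_sign,
                 noise_sd = noise_sd, dt = dt,
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Cluster membership vector implied by a synthetic spec
#' @param spec A [synthetic_spec()].
#' @return Integer vector assigning each node to its cluster.
#' @export
cluster_membership <- function(spec) {
  rep(seq_along(spec$cluster_sizes), spec$cluster_sizes)
}

#' Draw a modular signed ground-truth connectivity matrix
#'
#' Within-cluster ordered pairs receive an emulative (positive) coupling
#' with probability `density_within`, between-cluster pairs a non-emulative
#' (negative) one with probability `density_between`; magnitudes are
#' uniform on `weight_range`, self loops positive with probability
#' `self_loop_prob`. Bit-reproducible given the spec's seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A [signed_connectivity()] matrix with labels `n1..nN`.
#' @export
generate_modular_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  member <- cluster_membership(spec)
  n <- length(member)
  with_seed(spec$seed, {
    same <- outer(member, member, `==`)
    present <- matrix(stats::runif(n * n), n, n) <
      ifelse(same, spec$density_within, spec$density_between)
    w <- matrix(stats::runif(n * n, spec$weight_range[1], spec$weight_range[2]),
                n, n)
    sgn <- ifelse(same, spec$within_sign, spec$between_sign)
    A <- ifelse(present, w * sign(sgn), 0)
    diag(A) <- ifelse(stats::runif(n) < spec$self_loop_prob,
                      stats::runif(n, spec$weight_range[1], spec$weight_range[2]) *
                        sign(spec$within_sign),
                      0)
    signed_connectivity(A, labels = paste0("n", seq_len(n)))
  })
}

#' Generate a model trajectory with optional observation noise
#'
#' Integrates the replicator dynamics from a random interior (or given)
#' initial condition with the chosen scheme at the spec's sampling interval,
#' then adds i.i.d. Gaussian observation noise and clips the result into
#' `[eps, 1 - eps]`. With `scheme = "euler"` and zero noise the output
#' satisfies the estimator's forward-Euler relation exactly, which is what
#' makes noiseless parameter recovery exact.
#'
#' @param conn Ground-truth [signed_connectivity()].
#' @param spec A [synthetic_spec()] (supplies `dt`, `n_samples`,
#'   `noise_sd`, `seed`).
#' @param x0_mode `"random_interior"` (uniform on `[0.25, 0.75]`, seeded)
#'   or `"given"`.
#' @param x0 Initial condition when `x0_mode = "given"`.
#' @param scheme `"euler"` (discrete map, default) or `"rk4"`
#'   (continuous-time integration sampled on the grid).
#' @param eps Clipping margin after adding noise.
#' @return An [trajectory()] object.
#' @export
generate_trajectory <- function(conn, spec,
                                x0_mode = c("random_interior", "given"),
                                x0 = NULL, scheme = c("euler", "rk4"),
                                eps = 1e-9) {
  stopifnot(inherits(spec, "synthetic_spec"))
  x0_mode <- match.arg(x0_mode)
  scheme <- match.arg(scheme)
  n <- nrow(conn)
  with_seed(spec$seed + 1L, {
    if (x0_mode == "random_interior") {
      x0 <- stats::runif(n, 0.25, 0.75)
    } else {
      if (is.null(x0) || length(x0) != n) {
        stop("x0_mode = 'given' requires an x0 of length N", call. = FALSE)
      }
      if (any(x0 < 0 | x0 > 1)) stop("x0 must lie in [0, 1]", call. = FALSE)
    }
    states <- if (scheme == "euler") {
      euler_path(conn, x0, n_steps = spec$n_samples - 1L, dt = spec$dt,
                 eps = eps, clamp_full = TRUE)
    } else {
      s <- simulate_egnb(conn, x0, n_samples = spec$n_samples, dt = spec$dt)$states
      # same boundary policy as the Euler scheme: only samples that moved
      # since the previous one are pulled inside the clamp margin
      for (k in seq(2L, nrow(s))) {
        moved <- s[k, ] != s[k - 1L, ]
        s[k, moved] <- pmin(pmax(s[k, moved], eps), 1 - eps)
      }
      s
    }
    if (spec$noise_sd > 0) {
      states <- states + matrix(stats::rnorm(length(states), 0, spec$noise_sd),
                                nrow(states), ncol(states))
      states <- pmin(pmax(states, eps), 1 - eps)
    }
    colnames(states) <- node_labels(conn)
    trajectory(states, dt = spec$dt)
  })
}

#' Compare an estimated connectivity matrix with the ground truth
#'
#' @param conn_true,conn_est [signed_connectivity()] matrices with the same
#'   dimension and labels.
#' @param edge_floor Magnitude above which an estimate on a true-zero entry
#'   counts as a false edge (default 0.05).
#' @return List with `max_abs_error`, `rmse`,
#'   `sign_agreement_pct_on_nonzero` (over entries with nonzero truth; NA
#'   if none), `false_edge_rate` (over true-zero entries; NA if none).
#' @export
recovery_report <- function(conn_true, conn_est, edge_floor = 0.05) {
  if (!all(dim(conn_true) == dim(conn_est))) {
    stop("matrices must have identical dimensions", call. = FALSE)
  }
  if (!identical(node_labels(conn_true), node_labels(conn_est))) {
    stop("matrices must carry identical node labels", call. = FALSE)
  }
  Tm <- as_conn_matrix(conn_true)
  Em <- as_conn_matrix(conn_est)
  err <- Em - Tm
  nz <- Tm != 0
  list(max_abs_error = max(abs(err)),
       rmse = sqrt(mean(err^2)),
       sign_agreement_pct_on_nonzero =
         if (any(nz)) 100 * mean(sign(Em[nz]) == sign(Tm[nz])) else NA_real_,
       false_edge_rate =
         if (any(!nz)) mean(abs(Em[!nz]) > edge_floor) else NA_real_)
}
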