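# Shared fixtures and independent oracles for the test suite.

# Canonical two-node networks (Fig-1-style regimes).
two_node_emulative <- function(w = 1) {
  signed_connectivity(matrix(c(0, w, w, 0), 2, 2, byrow = TRUE))
}
two_node_nonemulative <- function(w = 1) {
  signed_connectivity(matrix(c(0, -w, -w, 0), 2, 2, byrow = TRUE))
}
two_node_mixed <- function(w = 1) {
  signed_connectivity(matrix(c(0, w, -w, 0), 2, 2, byrow = TRUE))
}

# Conserved quantity of the mixed-attitude two-node system (no self loops):
# dH/dt = 0 along exact solutions, by the chain rule on the replicator RHS.
two_node_invariant <- function(states) {
  -log(states[, 1] * (1 - states[, 1])) - log(states[, 2] * (1 - states[, 2]))
}

# Unit-scale modular spec used across identification/prediction tests.
unit_weight_spec <- function(seed, noise_sd = 0, dt = 0.02, n_samples = 500,
                             cluster_sizes = c(5L, 5L)) {
  synthetic_spec(cluster_sizes = cluster_sizes, weight_range = c(0.5, 1.5),
                 density_within = 0.9, density_between = 0.4,
                 self_loop_prob = 0.25, noise_sd = noise_sd, dt = dt,
                 n_samples = n_samples, seed = seed)
}

# Random dense signed network with entries uniform on [-wmax, wmax].
random_signed_network <- function(n, wmax = 1) {
  signed_connectivity(matrix(stats::runif(n * n, -wmax, wmax), n, n))
}

# Independent brute-force minimiser of the least squares functional
# F(theta) = ||Y - U theta||: conjugate gradient on the (convex quadratic)
# normal equations, started from zero, run to machine-precision residual.
# Exact for quadratics in at most dim(theta) iterations up to roundoff; it
# never touches the package's QR/solve path.
cg_minimise <- function(U, Y, maxit = 5000, tol = 1e-14) {
  A <- 2 * crossprod(U)
  b <- as.numeric(2 * crossprod(U, Y))
  th <- numeric(ncol(U))
  r <- b - as.numeric(A %*% th)
  p <- r
  rs <- sum(r * r)
  for (i in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    a <- rs / sum(p * Ap)
    th <- th + a * p
    r <- r - a * Ap
    rs2 <- sum(r * r)
    if (sqrt(rs2) < tol * max(1, sqrt(sum(b * b)))) break
    p <- r + (rs2 / rs) * p
    rs <- rs2
  }
  th
}
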