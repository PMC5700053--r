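test_that("BOLD scaling maps each node onto [delta, 1 - delta] invertibly", {
  raw <- cbind(c(0, 5, 10), c(-2, 1, 6))
  out <- scale_bold(raw, delta = 0.05)
  expect_equal(out$trajectory$states[, 1], c(0.05, 0.5, 0.95),
               ignore_attr = TRUE)
  expect_equal(range(out$trajectory$states[, 2]), c(0.05, 0.95))
  # a column already spanning [delta, 1 - delta] is unchanged
  pre <- cbind(seq(0.05, 0.95, length.out = 5), c(0.2, 0.05, 0.9, 0.95, 0.5))
  out2 <- scale_bold(pre, delta = 0.05)
  expect_equal(out2$trajectory$states, pre, ignore_attr = TRUE)
  # round trip to machine precision
  expect_equal(unscale_bold(out$trajectory, out$scaling), raw,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(scale_bold(cbind(1:3, rep(2, 3))), "n2")
  expect_error(scale_bold(raw, delta = 0.3), "delta")
})

test_that("regression system matches the hand-assembled discretization", {
  # T = 2, N = 1: single row x(1-x)(2x-1), response (x1 - x0)/dt
  x0 <- 0.3; x1 <- 0.4; dt <- 0.5
  tr <- trajectory(matrix(c(x0, x1), 2, 1), dt = dt)
  rs <- build_regression(tr)
  expect_equal(rs$blocks[[1]]$X, matrix(x0 * (1 - x0) * (2 * x0 - 1), 1, 1),
               ignore_attr = TRUE)
  expect_equal(rs$blocks[[1]]$y, (x1 - x0) / dt)
  # constant midpoint trajectory zeroes both regressors and responses
  trc <- trajectory(matrix(0.5, 6, 3), dt = 1)
  rsc <- build_regression(trc)
  for (b in rsc$blocks) {
    expect_equal(max(abs(b$X)), 0)
    expect_equal(max(abs(b$y)), 0)
  }
  # stacked dimensions: Y length N(T-1), U is N(T-1) x N^2, block diagonal
  set.seed(2)
  trr <- trajectory(matrix(runif(5 * 3, 0.2, 0.8), 5, 3), dt = 2)
  asm <- assemble_regression(build_regression(trr))
  expect_equal(length(asm$Y), 3 * 4)
  expect_equal(dim(asm$U), c(3 * 4, 9))
  # off-block entries are exactly zero
  expect_equal(max(abs(asm$U[1:4, 4:9])), 0)
  expect_error(build_regression(trajectory(matrix(c(0, 0.5), 2, 1), dt = 1)),
               "boundary")
})

test_that("central-difference scheme uses interior samples symmetrically", {
  set.seed(3)
  tr <- trajectory(matrix(runif(10 * 2, 0.2, 0.8), 10, 2), dt = 0.5)
  rs <- build_regression(tr, scheme = "central")
  expect_equal(length(rs$blocks[[1]]$y), 8)
  expect_equal(rs$blocks[[1]]$y[1],
               unname(tr$states[3, 1] - tr$states[1, 1]) / (2 * 0.5))
})

test_that("estimator recovers the generating matrix exactly without noise", {
  sp <- unit_weight_spec(seed = 5, dt = 0.01, n_samples = 200,
                         cluster_sizes = c(3L, 2L))
  net <- generate_modular_network(sp)
  tr <- generate_trajectory(net, sp)
  est <- estimate_connectivity(tr)
  rep <- recovery_report(net, est)
  expect_lt(rep$max_abs_error, 1e-8)
  expect_equal(rep$sign_agreement_pct_on_nonzero, 100)
})

test_that("zero response with ridge gives the zero matrix", {
  tr <- trajectory(matrix(0.3, 50, 2), dt = 1)
  est <- estimate_connectivity(tr, ridge = 1e-4)
  expect_equal(max(abs(unclass(est))), 0)
})

test_that("closed-form solution matches a brute-force convex minimiser", {
  devs <- sapply(1:5, function(s) {
    sp <- unit_weight_spec(seed = s, noise_sd = 0.01, dt = 0.02,
                           n_samples = 100, cluster_sizes = c(3L, 2L))
    net <- generate_modular_network(sp)
    tr <- generate_trajectory(net, sp)
    est <- estimate_connectivity(tr)
    asm <- assemble_regression(build_regression(tr))
    theta_cg <- cg_minimise(asm$U, asm$Y)
    max(abs(theta_cg - as.numeric(t(unclass(est)))))
  })
  expect_lt(max(devs), 1e-6)
})

test_that("per-node blocks and the stacked system give the same solution", {
  sp <- unit_weight_spec(seed = 9, noise_sd = 0.02, dt = 0.02,
                         n_samples = 80, cluster_sizes = c(3L, 2L))
  net <- generate_modular_network(sp)
  tr <- generate_trajectory(net, sp)
  est <- estimate_connectivity(tr)
  asm <- assemble_regression(build_regression(tr))
  theta_full <- qr.coef(qr(asm$U), asm$Y)
  expect_equal(as.numeric(t(unclass(est))), as.numeric(theta_full),
               tolerance = 1e-9)
})

test_that("the least squares solution is the unique minimum", {
  sp <- unit_weight_spec(seed = 13, noise_sd = 0.02, dt = 0.02,
                         n_samples = 80, cluster_sizes = c(3L, 2L))
  net <- generate_modular_network(sp)
  tr <- generate_trajectory(net, sp)
  est <- estimate_connectivity(tr)
  asm <- assemble_regression(build_regression(tr))
  theta_hat <- as.numeric(t(unclass(est)))
  F0 <- sum((asm$Y - asm$U %*% theta_hat)^2)
  set.seed(1)
  for (i in 1:20) {
    d <- rnorm(length(theta_hat))
    d <- d / sqrt(sum(d^2))
    expect_gt(sum((asm$Y - asm$U %*% (theta_hat + 0.01 * d))^2), F0)
  }
})

test_that("rank-deficient designs are reported with advice", {
  # two identical nodes make source columns collinear
  set.seed(4)
  x <- runif(30, 0.2, 0.8)
  m <- unname(cbind(x, x, runif(30, 0.2, 0.8)))
  tr <- trajectory(m, dt = 1)
  expect_error(estimate_connectivity(tr), "ridge")
  expect_silent(estimate_connectivity(tr, ridge = 1e-3))
})

test_that("fit quality is perfect on self-generated data", {
  sp <- unit_weight_spec(seed = 21, dt = 0.05, n_samples = 60,
                         cluster_sizes = c(3L, 2L))
  net <- generate_modular_network(sp)
  base <- simulate_egnb(net, runif(5, 0.3, 0.7), n_samples = 60, dt = 0.05)
  fq <- fit_quality(base, net)
  expect_lt(fq$rmse_overall, 1e-9)
  expect_equal(unname(fq$max_crosscorr_per_node), rep(1, 5),
               tolerance = 1e-9)
})

test_that("a zero matrix predicts the constant initial state", {
  set.seed(6)
  m <- matrix(runif(40 * 2, 0.2, 0.8), 40, 2)
  tr <- trajectory(m, dt = 1)
  fq <- fit_quality(tr, signed_connectivity(matrix(0, 2, 2)))
  expect_equal(unname(fq$rmse_per_node),
               sqrt(colMeans(sweep(m, 2, m[1, ])^2)), tolerance = 1e-12)
})

test_that("estimated dynamics track noiseless data nearly perfectly", {
  sp <- unit_weight_spec(seed = 31, dt = 0.02, n_samples = 180)
  net <- generate_modular_network(sp)
  tr <- generate_trajectory(net, sp)
  est <- estimate_connectivity(tr)
  fq <- fit_quality(tr, est)
  expect_true(all(fq$max_crosscorr_per_node >= 0.99, na.rm = TRUE))
})
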