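test_that("binning follows the indicator convention at breakpoints", {
  bp <- c(0.5, 1)
  expect_equal(bin_point(0.3, bp), 1L)
  expect_equal(bin_point(0.5, bp), 2L)      # c_1 <= x maps to the next bin
  bp5 <- seq(0.2, 1, by = 0.2)
  expect_equal(bin_point(1 - 1e-12, bp5), 5L)
  expect_equal(bin_point(c(0, 0.2, 0.999), bp5), c(1L, 2L, 5L))
  expect_error(bin_point(1, bp), "\\[0, 1\\)")
  expect_error(bin_point(-0.1, bp), "\\[0, 1\\)")
})

test_that("identifiability relabeling sorts the degree function stably", {
  out <- relabel_identifiable(c(0.5, 0.5),
                              matrix(c(0.8, 0.2, 0.2, 0.4), 2, 2))
  expect_equal(out$perm, c(2L, 1L))        # g = (0.5, 0.3) -> swap
  expect_equal(out$g, c(0.3, 0.5))
  expect_equal(out$theta, matrix(c(0.4, 0.2, 0.2, 0.8), 2, 2))
  # already sorted: identity
  sorted <- relabel_identifiable(c(0.5, 0.5),
                                 matrix(c(0.2, 0.3, 0.3, 0.8), 2, 2))
  expect_equal(sorted$perm, c(1L, 2L))
  # complete ties keep original order
  ties <- relabel_identifiable(rep(1 / 3, 3), matrix(0.4, 3, 3))
  expect_equal(ties$perm, 1:3)
})

test_that("graphon estimates are piecewise constant with nondecreasing g", {
  p <- make_homogeneous_params(2, 1, 0.9, 0.1)
  sim <- simulate_sbm(p, 80, seed = 14)
  z <- spectral_partition(sim$graph, 2, cluster_config(seed = 1))
  est <- estimate_graphon(sim$graph, z, "EB")
  g <- as.vector(est$theta %*% est$pi_hat)
  expect_true(all(diff(g) >= -1e-12))
  expect_equal(est$breakpoints[length(est$breakpoints)], 1)
  expect_true(all(diff(c(0, est$breakpoints)) > 0))
  # evaluator is total on [0,1)^2 and piecewise constant
  xs <- c(0.01, 0.45, 0.92)
  vals <- est$W(xs, xs)
  expect_true(all(vals >= 0 & vals <= 1))
  # K = 1: constant equal to the EB-smoothed density
  z1 <- eb_partition(rep(1L, 80))
  est1 <- estimate_graphon(sim$graph, z1, "EB")
  expect_equal(est1$W(0.1, 0.9), est1$W(0.7, 0.2))
})

test_that("relabeled estimates always have nondecreasing g across models", {
  spec <- graphon_spec(rho = 0.1, lambda = 2)
  for (t in 1:5) {
    sim <- simulate_graphon(spec, 60, seed = 40 + t)
    for (K in c(2, 4)) {
      z <- spectral_partition(sim$graph, K, cluster_config(seed = t))
      est <- estimate_graphon(sim$graph, z, "EB")
      g <- as.vector(est$theta %*% est$pi_hat)
      expect_true(all(diff(g) >= -1e-12))
    }
  }
})

test_that("graphon error matches the closed form for the constant estimate", {
  # truth rho lambda^2 (xy)^(lambda-1); constant estimate rho:
  # MSE = rho^2 (lambda^4 / (2 lambda - 1)^2 - 1)
  truth <- graphon_spec(rho = 0.1, lambda = 2)
  const <- list(W = function(x, y) 0.1 + 0 * x)
  closed <- 0.01 * (16 / 9 - 1)
  expect_equal(graphon_mse(truth, const, 500), closed, tolerance = 1e-4)
  # grid refinement changes the value negligibly
  expect_lt(abs(graphon_mse(truth, const, 800) -
                  graphon_mse(truth, const, 200)), 1e-4)
  # identical graphons: zero error
  expect_equal(graphon_mse(truth, truth, 300), 0)
})

test_that("estimated graphon integrates to the EB mean density", {
  spec <- graphon_spec(rho = 0.2, lambda = 1.5)
  sim <- simulate_graphon(spec, 100, seed = 3)
  z <- spectral_partition(sim$graph, 3, cluster_config(seed = 2))
  est <- estimate_graphon(sim$graph, z, "EB")
  res <- 400
  mid <- (seq_len(res) - 0.5) / res
  Wbar <- mean(est$W(matrix(mid, res, res), t(matrix(mid, res, res))))
  # mean of the piecewise-constant surface = sum pi_a pi_b theta_ab
  expect_equal(Wbar, sum(tcrossprod(est$pi_hat) * est$theta),
               tolerance = 1e-3)
})

test_that("grid export reproduces the estimate's block values", {
  spec <- graphon_spec(rho = 0.1, lambda = 2)
  sim <- simulate_graphon(spec, 60, seed = 13)
  z <- spectral_partition(sim$graph, 2, cluster_config(seed = 1))
  est <- estimate_graphon(sim$graph, z, "MLE")
  gr <- graphon_grid(est, 50)
  expect_equal(dim(gr), c(50, 50))
  expect_lte(length(unique(as.vector(gr))), 3)   # K(K+1)/2 distinct blocks
  expect_equal(gr[1, 1], est$W(0.01, 0.01))
})

test_that("graphon family validates its parameter constraint", {
  expect_error(graphon_spec(rho = 0.25, lambda = 3), "lambda")
  expect_silent(graphon_spec(rho = 0.25, lambda = 2))
  s <- graphon_spec(rho = 0.1, lambda = 2)
  expect_equal(s$W(1, 1), 0.4)   # rho lambda^2 at the corner
  expect_equal(s$W(0.3, 0.7), s$W(0.7, 0.3))
})
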