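test_that("marginal log-likelihood matches closed forms under the uniform prior", {
  # one diagonal block, n = 3 dyads, x = 1: uniform prior gives 1/((n+1) C(n,x))
  st <- make_stats(1, 3)
  expect_equal(marginal_loglik(st, 1, 1, "diagonal"), log(1 / 12))
  # two diagonal blocks (2,1) and (2,0): (1/6) * (1/3)
  st2 <- make_stats(c(1, 0), c(2, 2))
  expect_equal(marginal_loglik(st2, 1, 1, "diagonal"), log(1 / 18))
  # K = 1 has no off-diagonal blocks: empty sum
  expect_equal(marginal_loglik(make_stats(2, 5), 2, 7, "offdiagonal"), 0)
  expect_error(marginal_loglik(st, -1, 1, "diagonal"), "positive")
})

test_that("marginal log-likelihood equals numeric integration over the prior", {
  grids <- list(c(a = 1.7, b = 3.2), c(a = 0.4, b = 0.9), c(a = 12, b = 5))
  x <- c(1, 0, 5, 14)
  n <- c(3, 7, 12, 30)
  for (p in grids) {
    oracle <- sum(vapply(seq_along(x), function(i) {
      log(stats::integrate(function(t)
        t^x[i] * (1 - t)^(n[i] - x[i]) * stats::dbeta(t, p["a"], p["b"]),
        0, 1, rel.tol = 1e-12)$value)
    }, 0))
    val <- marginal_loglik(make_stats(x, n), p["a"], p["b"], "diagonal")
    expect_equal(val, oracle, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("hyperparameter fit matches a dense grid-search oracle", {
  # dispersed block rates: interior optimum, grid over [-6, 6]^2 suffices
  st <- make_stats(c(2, 8, 3), c(10, 10, 10))
  fit <- fit_hyperparams(st)
  expect_equal(fit$loglik_diag, grid_oracle(st, -6, 6), tolerance = 1e-3)
  expect_true(all(fit$converged))
  # near-identical rates: the optimum sits on the optimizer's box edge
  # (concentration ridge), so the oracle grid must span the same box
  st2 <- make_stats(c(2, 3, 2), c(10, 10, 10))
  fit2 <- fit_hyperparams(st2)
  expect_equal(fit2$loglik_diag, grid_oracle(st2, log(1e-6), log(1e6)),
               tolerance = 1e-3)
})

test_that("fitted hyperparameters recover a known Beta prior across blocks", {
  ratios <- vapply(1:10, function(r) {
    set.seed(800 + r)
    th <- stats::rbeta(200, 2, 5)
    x <- stats::rbinom(200, 50, th)
    fit <- fit_hyperparams(make_stats(x, rep(50, 200)))
    fit$hyperparams$alpha0 / fit$hyperparams$beta0
  }, 0)
  expect_true(all(abs(ratios - 2 / 5) / (2 / 5) < 0.25))
})

test_that("all-zero blocks drive the prior to its degenerate edge", {
  st <- make_stats(c(0, 0, 0), c(10, 10, 10))
  fit <- fit_hyperparams(st)
  expect_lt(fit$hyperparams$alpha0, 1e-4)
  expect_gt(fit$hyperparams$beta0, 1e3)
  # likelihood is monotone along the box edge toward the degenerate prior
  edge <- vapply(10^seq(0, -5, by = -1), function(a)
    marginal_loglik(st, a, 1e4, "diagonal"), 0)
  expect_true(all(diff(edge) > 0))
})

test_that("fitted likelihood is never below the uniform-prior value", {
  set.seed(21)
  for (r in 1:5) {
    x <- stats::rbinom(8, 25, stats::runif(1, 0.05, 0.9))
    st <- make_stats(x, rep(25, 8))
    fit <- fit_hyperparams(st)
    expect_gte(fit$loglik_diag, marginal_loglik(st, 1, 1, "diagonal"))
  }
})

test_that("shrinkage factors follow the capacity formula and its limits", {
  hp <- eb_hyperparams(2, 3)        # alpha + beta = 5
  st <- make_stats(c(1, 0), c(15, 0), x_off = 3, n_off = 15)
  eta <- shrinkage_factors(st, hp)
  expect_equal(eta[1, 1], 0.25)     # 5 / (5 + 15)
  expect_equal(eta[2, 2], 1)        # zero capacity: pure prior
  huge <- make_stats(5, 1e6)
  expect_lt(shrinkage_factors(huge, hp)[1, 1], 1e-5)
  # strict monotonicity in capacity
  etas <- vapply(c(1, 5, 25, 125), function(nn)
    shrinkage_factors(make_stats(0, nn), hp)[1, 1], 0)
  expect_true(all(diff(etas) < 0))
})

test_that("EB estimate is the posterior mean and matches its shrinkage form", {
  hp <- eb_hyperparams(2, 3)
  st <- make_stats(4, 10)
  est <- eb_theta(st, hp)
  expect_equal(est$theta[1, 1], (2 + 4) / (2 + 3 + 10))   # 0.4
  eta <- est$shrinkage[1, 1]
  expect_equal(eta, 1 / 3)
  expect_equal(est$theta[1, 1], eta * 2 / 5 + (1 - eta) * 4 / 10)
  # empty block: prior mean
  st0 <- make_stats(c(4, 0), c(10, 0), x_off = 1, n_off = 4)
  expect_equal(eb_theta(st0, hp)$theta[2, 2], 2 / 5)
  # vanishing prior: EB tends to the MLE
  tiny <- eb_hyperparams(1e-6, 1e-6)
  expect_equal(eb_theta(st, tiny)$theta[1, 1], 0.4, tolerance = 1e-6)
})

test_that("every EB entry lies between the block MLE and the prior mean", {
  p <- make_homogeneous_params(4, 1, 0.8, 0.15)
  sim <- simulate_sbm(p, 60, seed = 12)
  for (K in c(2, 4, 6)) {
    z <- spectral_partition(sim$graph, K, cluster_config(seed = K))
    st <- block_counts(sim$graph, z)
    fit <- fit_hyperparams(st)
    hp <- fit$hyperparams
    est <- eb_theta(st, hp)
    mle <- mle_theta(st)$theta
    prior <- matrix(hp$alpha1 / (hp$alpha1 + hp$beta1), z$K, z$K)
    diag(prior) <- hp$alpha0 / (hp$alpha0 + hp$beta0)
    lo <- pmin(mle, prior) - 1e-12
    hi <- pmax(mle, prior) + 1e-12
    ok <- est$theta >= lo & est$theta <= hi
    ok[st$capacities == 0] <- TRUE    # empty blocks sit at the prior mean
    expect_true(all(ok))
  }
})

test_that("relabeling permutes the EB estimate but not the fitted prior", {
  p <- make_homogeneous_params(3, 1, 0.8, 0.1)
  sim <- simulate_sbm(p, 45, seed = 6)
  z <- sim$partition
  set.seed(2)
  perm <- sample.int(z$K)
  z2 <- eb_partition(perm[z$labels], K = z$K)
  st1 <- block_counts(sim$graph, z)
  st2 <- block_counts(sim$graph, z2)
  f1 <- fit_hyperparams(st1)
  f2 <- fit_hyperparams(st2)
  expect_equal(unlist(f2$hyperparams), unlist(f1$hyperparams), tolerance = 1e-5)
  e1 <- eb_theta(st1, f1$hyperparams)$theta
  e2 <- eb_theta(st2, f1$hyperparams)$theta
  expect_equal(e2[perm, perm], e1)
})
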