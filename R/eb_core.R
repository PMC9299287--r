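#' Beta hyperparameters of the hierarchical block model
#'
#' The connectivity probabilities of diagonal (within-community) blocks are
#' modeled as draws from `Beta(alpha0, beta0)` and those of off-diagonal
#' blocks from `Beta(alpha1, beta1)`. Modeling the two sides separately
#' accommodates assortative and disassortative structure.
#'
#' @param alpha0,beta0 positive shape parameters of the diagonal-block prior.
#' @param alpha1,beta1 positive shape parameters of the off-diagonal prior.
#' @return A list of class `eb_hyperparams`.
#' @export
eb_hyperparams <- function(alpha0, beta0, alpha1 = alpha0, beta1 = beta0) {
  v <- c(alpha0 = alpha0, beta0 = beta0, alpha1 = alpha1, beta1 = beta1)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("all hyperparameters must be strictly positive and finite")
  structure(as.list(v), class = "eb_hyperparams")
}

#' @export
print.eb_hyperparams <- function(x, ...) {
  cat(sprintf(
    "<eb_hyperparams> diagonal Beta(%.4g, %.4g), off-diagonal Beta(%.4g, %.4g)\n",
    x$alpha0, x$beta0, x$alpha1, x$beta1))
  invisible(x)
}

side_counts <- function(stats, side) {
  side <- match.arg(side, c("diagonal", "offdiagonal"))
  if (side == "diagonal") {
    list(x = diag(stats$edge_counts), n = diag(stats$capacities))
  } else {
    up <- upper.tri(stats$edge_counts)
    list(x = stats$edge_counts[up], n = stats$capacities[up])
  }
}

#' Marginal log-likelihood of one side of the block model
#'
#' Integrating the block connectivity out of the Binomial likelihood under
#' its Beta prior gives, per block, `log B(alpha + x, beta + n - x) -
#' log B(alpha, beta)`; the side's marginal log-likelihood is the sum over
#' its blocks (diagonal blocks, or the strict upper triangle for the
#' off-diagonal side). Blocks with zero dyad capacity contribute exactly 0,
#' as does the off-diagonal side of a single-community partition.
#'
#' @param stats a [block_counts()] result.
#' @param alpha,beta positive prior shape parameters for this side.
#' @param side `"diagonal"` or `"offdiagonal"`.
#' @return The marginal log-likelihood value.
#' @export
marginal_loglik <- function(stats, alpha, beta,
                            side = c("diagonal", "offdiagonal")) {
  stopifnot(inherits(stats, "block_stats"))
  if (!is.finite(alpha) || !is.finite(beta) || alpha <= 0 || beta <= 0)
    stop("alpha and beta must be strictly positive")
  sc <- side_counts(stats, match.arg(side))
  if (length(sc$x) == 0L) return(0)
  sum(lbeta(alpha + sc$x, beta + sc$n - sc$x) - lbeta(alpha, beta))
}

# loglik and analytic gradient in (log alpha, log beta) for one side
side_negloglik <- function(p, x, n) {
  a <- exp(p[1L]); b <- exp(p[2L])
  -sum(lbeta(a + x, b + n - x) - lbeta(a, b))
}
side_negloglik_grad <- function(p, x, n) {
  a <- exp(p[1L]); b <- exp(p[2L])
  da <- sum(digamma(a + x) - digamma(a + b + n) - digamma(a) + digamma(a + b))
  db <- sum(digamma(b + n - x) - digamma(a + b + n) - digamma(b) + digamma(a + b))
  -c(da * a, db * b)
}

# method-of-moments start from the blockwise empirical rates, clipped to box
mom_start <- function(x, n, box) {
  r <- x[n > 0] / n[n > 0]
  p <- c(0, 0)  # log of (1, 1)
  if (length(r) >= 2L) {
    m <- mean(r); v <- stats::var(r)
    if (is.finite(v) && v > 0 && m > 0 && m < 1) {
      s <- m * (1 - m) / v - 1
      if (s > 0) p <- log(c(m * s, (1 - m) * s))
    }
  }
  pmin(pmax(p, box[1L]), box[2L])
}

fit_one_side <- function(x, n, cfg) {
  box <- cfg$box_log_bounds
  if (sum(n > 0) < 1L) {
    return(list(alpha = 1, beta = 1, loglik = 0, converged = TRUE,
                n_restarts_used = 0L))
  }
  run <- function(p0) {
    stats::optim(p0, side_negloglik, side_negloglik_grad, x = x, n = n,
                 method = "L-BFGS-B", lower = box[1L], upper = box[2L],
                 control = list(pgtol = cfg$tol, maxit = 500L))
  }
  best <- NULL
  used <- 0L
  # deterministic starts: method-of-moments, then the neutral uniform prior
  for (p0 in list(mom_start(x, n, box), c(0, 0))) {
    fit <- run(p0)
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  # seeded random restarts if the optimizer did not report convergence
  while (best$convergence != 0L && used < cfg$restarts) {
    used <- used + 1L
    p0 <- with_seed(cfg$seed + used,
                    stats::runif(2L, min = box[1L], max = box[2L]))
    fit <- run(p0)
    if (fit$value < best$value) best <- fit
  }
  list(alpha = exp(best$par[1L]), beta = exp(best$par[2L]),
       loglik = -best$value, converged = best$convergence == 0L,
       n_restarts_used = used)
}

#' Fit the prior hyperparameters by marginal maximum likelihood
#'
#' Maximizes [marginal_loglik()] separately for the diagonal and the
#' off-diagonal side with box-constrained quasi-Newton (L-BFGS-B) in
#' `(log alpha, log beta)`, which enforces positivity and conditions the
#' surface. Starts from a method-of-moments fit to the blockwise empirical
#' rates and from the uniform prior `(1, 1)`, keeping the better optimum
#' (so the fitted likelihood never falls below its value at `(1, 1)`);
#' seeded uniform restarts in the box are added if the optimizer fails to
#' converge. A side with no informative block (e.g. the off-diagonal side
#' when `K = 1`) is skipped and reported with the neutral values `(1, 1)`
#' and likelihood 0.
#'
#' @param stats a [block_counts()] result.
#' @param cfg optional list overriding `box_log_bounds` (length-2, in log
#'   space), `restarts`, `tol` (projected-gradient tolerance) and `seed`.
#' @return A list of class `eb_fit` with `hyperparams` ([eb_hyperparams()]),
#'   `loglik_diag`, `loglik_offdiag`, `converged` and `n_restarts_used`
#'   (each a named length-2 vector for the two sides).
#' @export
fit_hyperparams <- function(stats, cfg = list()) {
  stopifnot(inherits(stats, "block_stats"))
  defaults <- list(box_log_bounds = c(log(1e-6), log(1e6)),
                   restarts = 5L, tol = 1e-8, seed = 1L)
  cfg <- utils::modifyList(defaults, cfg)
  d <- side_counts(stats, "diagonal")
  o <- side_counts(stats, "offdiagonal")
  fd <- fit_one_side(d$x, d$n, cfg)
  fo <- fit_one_side(o$x, o$n, cfg)
  structure(list(
    hyperparams = eb_hyperparams(fd$alpha, fd$beta, fo$alpha, fo$beta),
    loglik_diag = fd$loglik,
    loglik_offdiag = fo$loglik,
    converged = c(diagonal = fd$converged, offdiagonal = fo$converged),
    n_restarts_used = c(diagonal = fd$n_restarts_used,
                        offdiagonal = fo$n_restarts_used)),
    class = "eb_fit")
}

#' @export
print.eb_fit <- function(x, ...) {
  print(x$hyperparams)
  cat(sprintf("  log-likelihood: diagonal %.4f, off-diagonal %.4f\n",
              x$loglik_diag, x$loglik_offdiag))
  invisible(x)
}

# per-block (alpha, beta) matrices by diagonal/off-diagonal position
hp_matrices <- function(K, hp) {
  A <- matrix(hp$alpha1, K, K); diag(A) <- hp$alpha0
  B <- matrix(hp$beta1, K, K); diag(B) <- hp$beta0
  list(A = A, B = B)
}

#' Shrinkage factors of the posterior-mean estimate
#'
#' `eta_ab = (alpha_d + beta_d) / (alpha_d + beta_d + n_ab)`: the weight the
#' posterior mean puts on the prior mean. It is 1 for empty blocks (pure
#' prior), decreases strictly in the dyad capacity, and vanishes as the
#' block grows (recovering the MLE).
#'
#' @param stats a [block_counts()] result.
#' @param hp an [eb_hyperparams()].
#' @return A symmetric `K x K` matrix with entries in `[0, 1]`.
#' @export
shrinkage_factors <- function(stats, hp) {
  stopifnot(inherits(stats, "block_stats"), inherits(hp, "eb_hyperparams"))
  m <- hp_matrices(stats$K, hp)
  (m$A + m$B) / (m$A + m$B + stats$capacities)
}

#' Empirical Bayes connectivity estimate
#'
#' The posterior mean of each block's connectivity under its side's Beta
#' prior, `(alpha_d + X^B_ab) / (alpha_d + beta_d + n_ab)` — equivalently
#' the shrinkage combination `eta * prior mean + (1 - eta) * MLE`. Empty
#' blocks are estimated by the prior mean.
#'
#' @param stats a [block_counts()] result.
#' @param hp an [eb_hyperparams()], typically from [fit_hyperparams()].
#' @return A `connectivity_estimate` with `method = "EB"` and the shrinkage
#'   matrix attached.
#' @export
eb_theta <- function(stats, hp) {
  stopifnot(inherits(stats, "block_stats"), inherits(hp, "eb_hyperparams"))
  m <- hp_matrices(stats$K, hp)
  theta <- (m$A + stats$edge_counts) / (m$A + m$B + stats$capacities)
  new_connectivity_estimate(theta, shrinkage_factors(stats, hp), method = "EB")
}

#' One-call empirical Bayes estimate for a graph and partition
#'
#' Convenience wrapper: block statistics, hyperparameter fit and posterior
#' means in one step.
#'
#' @param g an `eb_graph`.
#' @param z an `eb_partition`.
#' @param cfg optimizer configuration passed to [fit_hyperparams()].
#' @return A `connectivity_estimate` with the `eb_fit` attached as
#'   attribute `"fit"`.
#' @export
eb_connectivity <- function(g, z, cfg = list()) {
  stats <- block_counts(g, z)
  fit <- fit_hyperparams(stats, cfg)
  est <- eb_theta(stats, fit$hyperparams)
  attr(est, "fit") <- fit
  est
}
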