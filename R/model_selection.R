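#' Model selection configuration
#'
#' @param tau symmetric Dirichlet concentration on the community
#'   proportions. The default 1/2 is the Jeffreys prior; any value in
#'   `(0, 1]` is a standard non-informative choice, and a vector of
#'   per-community weights is accepted for informative priors.
#' @param criterion `"EB"` (penalized joint marginal likelihood, maximized)
#'   or `"CVRP"` (cluster-size cross-validation risk, minimized).
#' @param partition_prior form of the marginalized label-prior mass entering
#'   the criterion: `"sizes"` (default) uses the exchangeable
#'   Dirichlet-multinomial mass of the community-size vector, an
#'   `O(K log n)` term; `"assignment"` uses the mass of the specific label
#'   vector, which additionally charges the full `~ n H(pi)` assignment
#'   entropy against every multi-community model and in practice collapses
#'   selection to `K = 1` on weakly separated networks (see the methods
#'   vignette for why the size-vector form is the default).
#' @return A list of class `select_config`.
#' @export
select_config <- function(tau = 0.5, criterion = c("EB", "CVRP"),
                          partition_prior = c("sizes", "assignment")) {
  if (any(tau <= 0)) stop("tau must be positive")
  structure(list(tau = tau, criterion = match.arg(criterion),
                 partition_prior = match.arg(partition_prior)),
            class = "select_config")
}

#' Log marginal mass of a community assignment
#'
#' The probability of the observed label vector after integrating the
#' community proportions against a `Dirichlet(tau, ..., tau)` prior:
#' `log [ Gamma(K tau) prod_i Gamma(n_i + tau) /
#' (Gamma(n + K tau) prod_i Gamma(tau)) ]`, computed via `lgamma`. These
#' masses sum to 1 over all `K^n` label vectors (empty communities
#' included), so a raw size vector containing zeros is also accepted.
#'
#' @param z an `eb_partition`, or an integer vector of community sizes
#'   (zeros allowed) whose length is taken as `K`.
#' @param tau Dirichlet concentration, scalar or per-community vector.
#' @param assignment if `TRUE` (default) return the mass of the specific
#'   label vector; if `FALSE`, the mass of its size vector (the assignment
#'   mass times the multinomial coefficient `n! / prod(n_i!)`), which is
#'   what the selection criterion uses by default (see [select_config()]).
#' @return The log mass (a nonpositive number).
#' @export
dirichlet_logmass <- function(z, tau = 0.5, assignment = TRUE) {
  sizes <- if (inherits(z, "eb_partition")) z$sizes else as.integer(z)
  if (any(sizes < 0)) stop("community sizes must be nonnegative")
  K <- length(sizes)
  n <- sum(sizes)
  tau <- rep_len(tau, K)
  if (any(tau <= 0)) stop("tau must be positive")
  lm <- lgamma(sum(tau)) + sum(lgamma(sizes + tau)) -
    lgamma(n + sum(tau)) - sum(lgamma(tau))
  if (assignment) lm else lm + lgamma(n + 1) - sum(lgamma(sizes + 1))
}

#' Complexity penalty of the selection criterion
#'
#' `(1/2) [ (K - 1) log n + K (K + 1) / 2 * log(n (n - 1) / 2) ]`: half the
#' parameter count of the proportions times the log sample size for labels,
#' plus half the connectivity parameter count times the log dyad count —
#' the ICL-style penalty attached to the joint marginal likelihood.
#'
#' @param K number of communities.
#' @param n number of nodes.
#' @return The penalty value (nonnegative for `n >= 2`).
#' @export
selection_penalty <- function(K, n) {
  0.5 * ((K - 1) * log(n) + K * (K + 1) / 2 * log(n * (n - 1) / 2))
}

#' Score one candidate partition
#'
#' The goodness-of-fit term `J_Z` is the fitted diagonal plus off-diagonal
#' marginal log-likelihood (hyperparameters estimated by
#' [fit_hyperparams()]) plus the Dirichlet log mass of the assignment; the
#' criterion total is `J_Z` minus [selection_penalty()]. The cluster-size
#' cross-validation risk (CVRP) is attached for comparison.
#'
#' @param g an `eb_graph`.
#' @param z an `eb_partition`.
#' @param cfg a [select_config()].
#' @param fit_cfg optimizer configuration passed to [fit_hyperparams()].
#' @return A list of class `model_score` with `K`, `J_Z`, `penalty`,
#'   `total` (= `J_Z - penalty`), `cvrp`, and the `eb_fit` as `fit`.
#' @export
joint_score <- function(g, z, cfg = select_config(), fit_cfg = list()) {
  stopifnot(inherits(g, "eb_graph"), inherits(z, "eb_partition"))
  stats <- block_counts(g, z)
  fit <- fit_hyperparams(stats, fit_cfg)
  J_Z <- fit$loglik_diag + fit$loglik_offdiag +
    dirichlet_logmass(z, cfg$tau,
                      assignment = cfg$partition_prior == "assignment")
  penalty <- selection_penalty(z$K, g$n)
  structure(list(K = z$K, J_Z = J_Z, penalty = penalty,
                 total = J_Z - penalty, cvrp = cvrp_risk(z), fit = fit),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  cat(sprintf("<model_score> K = %d, J_Z = %.3f, penalty = %.3f, total = %.3f, cvrp = %.4f\n",
              x$K, x$J_Z, x$penalty, x$total, x$cvrp))
  invisible(x)
}

#' Cluster-size cross-validation risk (CVRP)
#'
#' `2K/(n-1) - (n+1)K/(n-1) * sum_i (n_i/n)^2`, a baseline model-selection
#' risk that depends only on the cluster sizes; the selected `K` minimizes
#' it. For `K = 1` the value is exactly -1.
#'
#' @param z an `eb_partition`.
#' @return The risk value.
#' @export
cvrp_risk <- function(z) {
  stopifnot(inherits(z, "eb_partition"))
  n <- length(z$labels)
  if (n == 1L) stop("CVRP is undefined for a single node")
  K <- z$K
  2 * K / (n - 1) - (n + 1) * K / (n - 1) * sum((z$sizes / n)^2)
}

#' Select the best partition among candidates
#'
#' Scores every candidate with [joint_score()] and returns the winner:
#' the maximal `total` under the EB criterion, or the minimal `cvrp` under
#' CVRP. Ties are broken toward the smallest realized `K` (parsimony).
#'
#' @param g an `eb_graph`.
#' @param partitions non-empty list of `eb_partition` candidates.
#' @param cfg a [select_config()].
#' @param fit_cfg optimizer configuration passed to [fit_hyperparams()].
#' @return A list with `partition` (the winner), `index` (its position in
#'   `partitions`), and `scores` (list of `model_score`, one per candidate).
#' @export
select_partition <- function(g, partitions, cfg = select_config(),
                             fit_cfg = list()) {
  if (length(partitions) == 0L) stop("no candidate partitions")
  scores <- lapply(partitions, joint_score, g = g, cfg = cfg,
                   fit_cfg = fit_cfg)
  Ks <- vapply(scores, `[[`, 0, "K")
  crit <- switch(cfg$criterion,
                 EB = vapply(scores, `[[`, 0, "total"),
                 CVRP = -vapply(scores, `[[`, 0, "cvrp"))
  best <- max(crit)
  # ties (exact) broken toward the smallest realized K, then first listed
  cand <- which(crit == best)
  index <- cand[which.min(Ks[cand])]
  list(partition = partitions[[index]], index = index, scores = scores)
}

#' Tabulate candidate scores
#'
#' @param scores list of `model_score` as returned by [select_partition()].
#' @return A data frame with columns `K`, `J_Z`, `penalty`, `total`, `cvrp`.
#' @export
score_table <- function(scores) {
  data.frame(K = vapply(scores, `[[`, 0, "K"),
             J_Z = vapply(scores, `[[`, 0, "J_Z"),
             penalty = vapply(scores, `[[`, 0, "penalty"),
             total = vapply(scores, `[[`, 0, "total"),
             cvrp = vapply(scores, `[[`, 0, "cvrp"))
}
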