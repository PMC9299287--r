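#' Node-level mean squared error of a connectivity estimate
#'
#' Both the estimate and the truth are expanded to the node level through
#' their own partitions (`Theta'_ij = theta_{Z(i) Z(j)}`), so community
#' label switching is irrelevant; the squared differences are averaged over
#' the `n (n - 1)` ordered off-diagonal pairs.
#'
#' @param est a `connectivity_estimate` (or bare `K x K` matrix).
#' @param z the `eb_partition` the estimate is indexed by.
#' @param truth_theta the true `K* x K*` connectivity matrix.
#' @param z_true true community labels: an `eb_partition` or an integer
#'   vector (raw labels referencing possibly-empty communities are fine).
#' @return The mean squared error.
#' @export
sbm_mse <- function(est, z, truth_theta, z_true) {
  theta <- if (inherits(est, "connectivity_estimate")) est$theta else est
  zl <- if (inherits(z, "eb_partition")) z$labels else as.integer(z)
  tl <- if (inherits(z_true, "eb_partition")) z_true$labels else as.integer(z_true)
  if (length(zl) != length(tl))
    stop("estimate and truth partitions cover different node sets")
  n <- length(zl)
  D <- (theta[zl, zl, drop = FALSE] - truth_theta[tl, tl, drop = FALSE])^2
  (sum(D) - sum(diag(D))) / (n * (n - 1))
}

#' Number of blocks minimizing the MLE's error
#'
#' The reference community count for model selection on graphons: the `K`
#' whose blockwise MLE attains the smallest mean squared error. Ties are
#' broken toward the smallest `K`.
#'
#' @param mse_by_k named numeric vector mapping `K` to the MLE's MSE.
#' @return The minimizing `K` (integer).
#' @export
k_tilde <- function(mse_by_k) {
  if (length(mse_by_k) == 0L) stop("empty MSE map")
  Ks <- as.integer(names(mse_by_k))
  if (anyNA(Ks)) stop("mse_by_k must be named by integer K")
  o <- order(Ks)
  Ks <- Ks[o]; v <- mse_by_k[o]
  Ks[which.min(v)]  # which.min takes the first (smallest K) on ties
}

#' Mean absolute deviation of selected community counts
#'
#' `E = mean(|K_hat_t - reference_t|)`; the reference may be a scalar
#' (true `K*`) or a per-replicate vector (e.g. per-graph `K~`).
#'
#' @param k_hat integer vector of selected counts.
#' @param reference scalar or vector of reference counts.
#' @return The mean absolute deviation.
#' @export
deviation_metric <- function(k_hat, reference) {
  if (length(reference) != 1L && length(reference) != length(k_hat))
    stop("reference must be scalar or match length(k_hat)")
  mean(abs(k_hat - reference))
}

#' Held-out dyad log-likelihood
#'
#' Splits the nodes into an observed set and a test set by seeded sampling
#' and evaluates the Bernoulli log-likelihood of every dyad with at least
#' one test endpoint under a connectivity estimate indexed by the true
#' labels. The estimate is expected to have been fit on the observed
#' subgraph by the caller. A degenerate probability in `{0, 1}` that
#' contradicts an observation yields `-Inf` (not an error).
#'
#' @param g an `eb_graph`.
#' @param est_theta `K x K` probability matrix indexed by the true labels.
#' @param z_true true labels (`eb_partition` or integer vector).
#' @param train_fraction fraction of nodes in the observed set, in (0, 1).
#' @param seed RNG seed for the split.
#' @return A list with `loglik`, `train` and `test` node index vectors.
#' @export
test_likelihood <- function(g, est_theta, z_true, train_fraction = 0.7,
                            seed = 1L) {
  stopifnot(inherits(g, "eb_graph"),
            train_fraction > 0, train_fraction < 1)
  tl <- if (inherits(z_true, "eb_partition")) z_true$labels else as.integer(z_true)
  n <- g$n
  train <- with_seed(seed, sort(sample.int(n, round(train_fraction * n))))
  test <- setdiff(seq_len(n), train)
  P <- est_theta[tl, tl, drop = FALSE]
  is_test <- seq_len(n) %in% test
  up <- upper.tri(P)
  eval_dyads <- up & (outer(is_test, is_test, "|"))
  x <- g$adjacency[eval_dyads]
  p <- P[eval_dyads]
  ll <- sum(ifelse(x == 1L, log(p), log1p(-p)))
  list(loglik = ll, train = train, test = test)
}

#' Simulation scenario configuration
#'
#' @param model one of `"m1"` (dense homogeneous), `"m2"` (sparse
#'   homogeneous), `"m1s"`/`"m2s"` (dense/sparse heterogeneous, per-network
#'   connectivities drawn from uniform ranges), `"graphon"` (the
#'   `rho lambda^2 (xy)^(lambda-1)` family).
#' @param n number of nodes.
#' @param K_star true community count (SBM models).
#' @param rho sparsity scale; defaults: 1 for `m1`/`m1s`, 0.2 for
#'   `m2`/`m2s`, 0.1 for `graphon`.
#' @param lambda within-community rate (homogeneous SBM) or concentration
#'   (graphon).
#' @param eps between-community rate (homogeneous SBM).
#' @param replicates number of independent networks.
#' @param seed master seed; each replicate derives its own stream.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(model = c("m1", "m2", "m1s", "m2s", "graphon"),
                       n = 200L, K_star = 10L, rho = NULL,
                       lambda = NULL, eps = 0.1, replicates = 20L,
                       seed = 1L) {
  model <- match.arg(model)
  if (is.null(rho))
    rho <- switch(model, m1 = 1, m1s = 1, m2 = 0.2, m2s = 0.2, graphon = 0.1)
  if (is.null(lambda))
    lambda <- if (model == "graphon") 2 else 0.9
  structure(list(model = model, n = as.integer(n),
                 K_star = as.integer(K_star), rho = rho, lambda = lambda,
                 eps = eps, replicates = as.integer(replicates),
                 seed = as.integer(seed)),
            class = "sim_config")
}

simulate_replicate <- function(cfg, t) {
  s <- replicate_seed(cfg$seed, t)
  if (cfg$model == "graphon") {
    spec <- graphon_spec(rho = cfg$rho, lambda = cfg$lambda)
    sim <- simulate_graphon(spec, cfg$n, seed = s)
    list(graph = sim$graph, truth = spec, labels = NULL)
  } else {
    params <- switch(cfg$model,
      m1 = , m2 = make_homogeneous_params(cfg$K_star, cfg$rho, cfg$lambda,
                                          cfg$eps),
      m1s = , m2s = sample_heterogeneous_params(cfg$K_star, cfg$rho,
                                                seed = s + 1L))
    sim <- simulate_sbm(params, cfg$n, seed = s + 2L)
    list(graph = sim$graph, truth = params, labels = sim$labels)
  }
}

#' Run a full simulation experiment
#'
#' For each replicate: simulate a network, build candidate partitions over
#' `cluster_cfg$k_range`, compute the MLE and EB connectivity estimates and
#' their errors at every candidate (node-level MSE against the planted
#' connectivity for block models; integrated squared error against the true
#' graphon after identifiability relabeling for graphon models), locate the
#' MLE-error-minimizing `K~`, and select `K^` by both the penalized EB
#' criterion and the CVRP baseline. Fully deterministic given
#' `sim_cfg$seed`.
#'
#' @param scenario a [sim_config()].
#' @param cluster_cfg a [cluster_config()].
#' @param select_cfg a [select_config()].
#' @param fit_cfg optimizer configuration for [fit_hyperparams()].
#' @param resolution grid resolution for graphon error integrals.
#' @return A list of class `eval_report`: `per_replicate` (data frame with
#'   `k_hat_eb`, `k_hat_cvrp`, `k_tilde`), `mse_mle` and `mse_eb`
#'   (replicate x candidate matrices, columns named by realized `K`),
#'   `E_Kstar` and `E_Ktilde` (named vectors for the EB and CVRP criteria;
#'   `E_Kstar` only for block models), and `freq_eb` (frequency table of
#'   the EB-selected `K^`).
#' @export
run_experiment <- function(scenario, cluster_cfg = cluster_config(),
                           select_cfg = select_config(), fit_cfg = list(),
                           resolution = 200L) {
  stopifnot(inherits(scenario, "sim_config"))
  M <- scenario$replicates
  nk <- length(cluster_cfg$k_range)
  mse_mle <- matrix(NA_real_, M, nk)
  mse_eb <- matrix(NA_real_, M, nk)
  realized <- matrix(NA_integer_, M, nk)
  per <- data.frame(t = seq_len(M), k_hat_eb = NA_integer_,
                    k_hat_cvrp = NA_integer_, k_tilde = NA_integer_)
  for (t in seq_len(M)) {
    rep_t <- simulate_replicate(scenario, t)
    g <- rep_t$graph
    ccfg <- cluster_cfg
    ccfg$seed <- replicate_seed(scenario$seed, t) + 3L
    parts <- candidate_partitions(g, ccfg)
    sel <- select_partition(g, parts, select_config(tau = select_cfg$tau,
                                                    criterion = "EB"),
                            fit_cfg = fit_cfg)
    Ks <- vapply(sel$scores, `[[`, 0, "K")
    realized[t, ] <- as.integer(Ks)
    cv <- vapply(sel$scores, `[[`, 0, "cvrp")
    cand_cv <- which(cv == min(cv))
    per$k_hat_eb[t] <- Ks[sel$index]
    per$k_hat_cvrp[t] <- Ks[cand_cv[which.min(Ks[cand_cv])]]
    for (i in seq_len(nk)) {
      z <- parts[[i]]
      if (scenario$model == "graphon") {
        mse_mle[t, i] <- graphon_mse(rep_t$truth,
                                     estimate_graphon(g, z, "MLE"),
                                     resolution)
        mse_eb[t, i] <- graphon_mse(rep_t$truth,
                                    estimate_graphon(g, z, "EB", fit_cfg),
                                    resolution)
      } else {
        stats <- block_counts(g, z)
        hp <- sel$scores[[i]]$fit$hyperparams
        mse_mle[t, i] <- sbm_mse(mle_theta(stats), z,
                                 rep_t$truth$theta_star, rep_t$labels)
        mse_eb[t, i] <- sbm_mse(eb_theta(stats, hp), z,
                                rep_t$truth$theta_star, rep_t$labels)
      }
    }
    curve <- mse_mle[t, ]
    names(curve) <- Ks
    per$k_tilde[t] <- k_tilde(curve)
  }
  report <- list(
    scenario = scenario,
    per_replicate = per,
    mse_mle = mse_mle, mse_eb = mse_eb, realized_K = realized,
    E_Ktilde = c(EB = deviation_metric(per$k_hat_eb, per$k_tilde),
                 CVRP = deviation_metric(per$k_hat_cvrp, per$k_tilde)),
    freq_eb = table(factor(per$k_hat_eb, levels = cluster_cfg$k_range)))
  if (scenario$model != "graphon")
    report$E_Kstar <- c(EB = deviation_metric(per$k_hat_eb, scenario$K_star),
                        CVRP = deviation_metric(per$k_hat_cvrp,
                                                scenario$K_star))
  class(report) <- "eval_report"
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> model %s, n = %d, %d replicates\n",
              x$scenario$model, x$scenario$n, x$scenario$replicates))
  if (!is.null(x$E_Kstar))
    cat(sprintf("  E_K*: EB %.3f, CVRP %.3f\n",
                x$E_Kstar["EB"], x$E_Kstar["CVRP"]))
  cat(sprintf("  E_K~: EB %.3f, CVRP %.3f\n",
              x$E_Ktilde["EB"], x$E_Ktilde["CVRP"]))
  invisible(x)
}
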