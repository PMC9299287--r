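#' Clustering configuration
#'
#' @param k_range integer vector of candidate community counts.
#' @param seed RNG seed controlling k-means initialization.
#' @param regularizer nonnegative degree-regularization constant; the value
#'   `regularizer * mean(degree) / n` is added to every dyad of the
#'   adjacency before Laplacian normalization, which keeps the spectral
#'   embedding stable on sparse graphs and for isolated nodes.
#' @param kmeans_restarts number of random k-means starts.
#' @param refine if `TRUE` (default) the k-means labels are polished by a
#'   mean-field EM pass on the block-model likelihood (see
#'   [refine_partition()]); spectral embeddings place nodes well in easy
#'   regimes but likelihood refinement is what recovers weakly separated
#'   communities.
#' @param refine_restarts EM restarts from perturbed initializations (the
#'   best complete-data likelihood wins).
#' @param refine_iters maximum EM sweeps per restart.
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(k_range = 1:20, seed = 1L, regularizer = 1,
                           kmeans_restarts = 20L, refine = TRUE,
                           refine_restarts = 3L, refine_iters = 100L) {
  stopifnot(all(k_range >= 1L), regularizer >= 0, kmeans_restarts >= 1L)
  structure(list(k_range = as.integer(sort(unique(k_range))),
                 seed = as.integer(seed),
                 regularizer = regularizer,
                 kmeans_restarts = as.integer(kmeans_restarts),
                 refine = isTRUE(refine),
                 refine_restarts = as.integer(refine_restarts),
                 refine_iters = as.integer(refine_iters)),
            class = "cluster_config")
}

# Run expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Top-k eigenvectors of the regularized, symmetrically normalized adjacency.
# Computed once for the largest k needed and cached by callers. A solver
# failure is retried once with a stronger regularizer before giving up.
spectral_embedding <- function(g, regularizer) {
  decompose <- function(reg) {
    A <- g$adjacency
    n <- g$n
    dbar <- mean(rowSums(A))
    A <- A + max(reg, 1e-3) * dbar / n
    s <- 1 / sqrt(rowSums(A))
    L <- A * tcrossprod(s)        # D^{-1/2} (A + tau*dbar/n) D^{-1/2}
    eigen(L, symmetric = TRUE)$vectors
  }
  tryCatch(decompose(regularizer), error = function(e) {
    tryCatch(decompose(10 * regularizer + 1), error = function(e2) {
      stop("eigendecomposition failed after regularizer retry: ",
           conditionMessage(e2))
    })
  })
}

kmeans_partition <- function(U, k, seed, restarts) {
  for (attempt in 0:5) {
    km <- with_seed(seed + attempt, {
      # Quick-TRANSfer warnings on hard embeddings are routine; the EM
      # refinement downstream does not depend on k-means converging fully
      suppressWarnings(
        stats::kmeans(U, centers = k, nstart = restarts, iter.max = 100L))
    })
    if (length(unique(km$cluster)) == k)
      return(compact_partition(km$cluster))
  }
  # all restarts produced an empty cluster: compact what we have
  compact_partition(km$cluster)
}

# complete-data SBM profile log-likelihood of hard labels (smoothed rates)
hard_loglik <- function(A, labels, K) {
  n <- nrow(A)
  C <- matrix(0, n, K); C[cbind(seq_len(n), labels)] <- 1
  M <- crossprod(C, A) %*% C; diag(M) <- diag(M) / 2
  sz <- colSums(C)
  cap <- tcrossprod(sz); diag(cap) <- sz * (sz - 1) / 2
  th <- (M + 0.5) / (cap + 1)
  up <- upper.tri(M, diag = TRUE)
  sum(M[up] * log(th[up]) + (cap[up] - M[up]) * log1p(-th[up]))
}

# one mean-field EM run: soft responsibilities, point-estimate (pi, theta);
# stops when responsibilities settle or the hard labels are stable
em_run <- function(A, z0, K, iters) {
  n <- nrow(A)
  Q <- matrix(0.1 / K, n, K)
  Q[cbind(seq_len(n), z0)] <- Q[cbind(seq_len(n), z0)] + 0.9
  hard <- z0
  stable <- 0L
  for (it in seq_len(iters)) {
    Nc <- colSums(Q)
    pi_c <- pmax(Nc / n, 1e-12)
    E <- crossprod(Q, A) %*% Q
    Cap <- tcrossprod(Nc) - crossprod(Q)
    th <- (E + 0.5) / (Cap + 1)
    S <- A %*% Q
    Tm <- matrix(Nc, n, K, byrow = TRUE) - Q - S
    G <- matrix(log(pi_c), n, K, byrow = TRUE) +
      S %*% t(log(th)) + Tm %*% t(log1p(-th))
    G <- G - apply(G, 1, max)
    Qn <- exp(G)
    Qn <- Qn / rowSums(Qn)
    delta <- max(abs(Qn - Q))
    Q <- Qn
    hard_new <- max.col(Q, ties.method = "first")
    stable <- if (identical(hard_new, hard)) stable + 1L else 0L
    hard <- hard_new
    if (delta < 1e-6 || stable >= 5L) break
  }
  hard
}

#' Likelihood refinement of a hard partition
#'
#' Polishes node labels by mean-field EM on the block-model likelihood with
#' point estimates of the community proportions and connectivities
#' (lightly smoothed to keep log rates finite). Several restarts are run —
#' the given labels plus seeded 20%-perturbations of them — and the labels
#' with the best complete-data profile likelihood are kept. Communities
#' emptied by the refinement are removed by compaction.
#'
#' @param g an `eb_graph`.
#' @param z an `eb_partition` to refine.
#' @param cfg a [cluster_config()] (uses `refine_restarts`, `refine_iters`
#'   and `seed`).
#' @return A refined `eb_partition` (realized community count may be lower).
#' @export
refine_partition <- function(g, z, cfg = cluster_config()) {
  stopifnot(inherits(g, "eb_graph"), inherits(z, "eb_partition"))
  K <- z$K
  if (K == 1L) return(z)
  A <- g$adjacency
  n <- g$n
  best <- z$labels
  best_ll <- hard_loglik(A, best, K)
  for (r in seq_len(cfg$refine_restarts)) {
    z0 <- if (r == 1L) z$labels else with_seed(cfg$seed + 7L * K + r, {
      zi <- z$labels
      idx <- sample.int(n, ceiling(0.2 * n))
      zi[idx] <- sample.int(K, length(idx), replace = TRUE)
      zi
    })
    zr <- em_run(A, z0, K, cfg$refine_iters)
    ll <- hard_loglik(A, zr, K)
    if (ll > best_ll) {
      best <- zr
      best_ll <- ll
    }
  }
  compact_partition(best)
}

#' Partition a graph by regularized spectral clustering
#'
#' Computes the symmetrically normalized Laplacian spectrum of the
#' degree-regularized adjacency, row-normalizes the leading `k`
#' eigenvectors, and clusters the embedded nodes with k-means. For `k = 1`
#' the trivial single-community partition is returned without computation.
#'
#' @param g an `eb_graph`.
#' @param k requested number of communities (`1 <= k <= n`).
#' @param cfg a [cluster_config()].
#' @param embedding optional precomputed eigenvector matrix from a previous
#'   call (all `n` columns); callers scoring several `k` on one graph can
#'   pass it to avoid repeated eigendecompositions.
#' @return An `eb_partition` with at most `k` communities (fewer only if
#'   k-means repeatedly returns an empty cluster, in which case the realized
#'   count is reported after compaction).
#' @export
spectral_partition <- function(g, k, cfg = cluster_config(), embedding = NULL) {
  stopifnot(inherits(g, "eb_graph"))
  k <- as.integer(k)
  if (k > g$n) stop("k exceeds the number of nodes")
  if (k == 1L) return(eb_partition(rep(1L, g$n)))
  V <- if (is.null(embedding)) spectral_embedding(g, cfg$regularizer) else embedding
  U <- V[, seq_len(k), drop = FALSE]
  rn <- sqrt(rowSums(U^2))
  rn[rn == 0] <- 1
  U <- U / rn
  z <- kmeans_partition(U, k, cfg$seed + 1000L * k, cfg$kmeans_restarts)
  if (cfg$refine) z <- refine_partition(g, z, cfg)
  z
}

#' Candidate partitions over a range of community counts
#'
#' One spectral partition per value in `cfg$k_range`, sharing a single
#' eigendecomposition of the graph. Partitions are reported with their
#' realized community count, which can fall below the requested one when
#' k-means compaction removes empty clusters.
#'
#' @param g an `eb_graph`.
#' @param cfg a [cluster_config()].
#' @return A list of `eb_partition`, in the order of `cfg$k_range`.
#' @export
candidate_partitions <- function(g, cfg = cluster_config()) {
  stopifnot(inherits(g, "eb_graph"))
  kmax <- max(cfg$k_range)
  if (kmax > g$n) stop("k_range exceeds the number of nodes")
  V <- if (kmax > 1L) spectral_embedding(g, cfg$regularizer) else NULL
  lapply(cfg$k_range, function(k) spectral_partition(g, k, cfg, embedding = V))
}
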