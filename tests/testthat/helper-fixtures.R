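# Build a block_stats object directly from per-block counts: diagonal
# entries first, then the upper-triangle off-diagonal entries (row-major).
make_stats <- function(x_diag, n_diag, x_off = integer(0), n_off = integer(0)) {
  K <- length(x_diag)
  ec <- diag(x_diag, K)
  cap <- diag(n_diag, K)
  if (K >= 2 && length(x_off) > 0) {
    ec[upper.tri(ec)] <- x_off
    ec[lower.tri(ec)] <- t(ec)[lower.tri(ec)]
    cap[upper.tri(cap)] <- n_off
    cap[lower.tri(cap)] <- t(cap)[lower.tri(cap)]
  }
  structure(list(K = as.integer(K), edge_counts = ec, capacities = cap),
            class = "block_stats")
}

# Graph from an explicit edge list (1-based node indices)
graph_from_edges <- function(n, edges) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- 1L
    adj[e[2], e[1]] <- 1L
  }
  eb_graph(adj)
}

# Two disjoint k-cliques
two_cliques <- function(size = 5) {
  n <- 2 * size
  adj <- matrix(0L, n, n)
  adj[1:size, 1:size] <- 1L
  adj[(size + 1):n, (size + 1):n] <- 1L
  diag(adj) <- 0L
  eb_graph(adj)
}

adjusted_rand <- function(a, b) mclust::adjustedRandIndex(a, b)

# Two-stage grid-search oracle for the diagonal-side marginal likelihood
grid_oracle <- function(st, lo, hi, n1 = 400, n2 = 200) {
  eval_grid <- function(ga, gb) {
    outer(ga, gb, function(a, b)
      mapply(function(ai, bi) marginal_loglik(st, exp(ai), exp(bi),
                                              "diagonal"), a, b))
  }
  gr <- seq(lo, hi, length.out = n1)
  vals <- eval_grid(gr, gr)
  top <- which(vals == max(vals), arr.ind = TRUE)[1, ]
  h <- gr[2] - gr[1]
  clamp <- function(x) pmin(pmax(x, lo), hi)
  gr2a <- seq(clamp(gr[top[1]] - 2 * h), clamp(gr[top[1]] + 2 * h),
              length.out = n2)
  gr2b <- seq(clamp(gr[top[2]] - 2 * h), clamp(gr[top[2]] + 2 * h),
              length.out = n2)
  max(eval_grid(gr2a, gr2b))
}
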