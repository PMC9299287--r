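#' Homogeneous (affiliation) block-model parameters
#'
#' The planted connectivity matrix has `rho * lambda` on the diagonal and
#' `rho * eps` off the diagonal, with uniform community probabilities
#' `1/K_star`. The dense benchmark design uses `lambda = 0.9, eps = 0.1,
#' rho = 1`; the sparse design scales the same matrix by `rho = 0.2`.
#'
#' @param K_star true number of communities.
#' @param rho sparsity scale in `(0, 1]`.
#' @param lambda within-community base rate.
#' @param eps between-community base rate; `eps < lambda` for an
#'   assortative model (equality is accepted with a warning, giving a
#'   rank-degenerate model).
#' @return A list of class `sbm_params` with `K_star`, `pi`, `theta_star`.
#' @export
make_homogeneous_params <- function(K_star, rho = 1, lambda = 0.9, eps = 0.1) {
  if (rho * lambda > 1 || rho * eps < 0)
    stop("need 0 <= rho*eps and rho*lambda <= 1")
  if (eps > lambda) stop("need eps <= lambda")
  if (eps == lambda) warning("eps == lambda: communities are indistinguishable")
  theta <- matrix(rho * eps, K_star, K_star)
  diag(theta) <- rho * lambda
  structure(list(K_star = as.integer(K_star),
                 pi = rep(1 / K_star, K_star), theta_star = theta),
            class = "sbm_params")
}

#' Heterogeneous block-model parameters
#'
#' Diagonal connectivities are drawn independently from `U(0.5, 0.9)` and
#' off-diagonal ones from `U(0.3, 0.5)` (drawn on the upper triangle and
#' mirrored, since the graph is undirected), all scaled by `rho`.
#'
#' @param K_star true number of communities.
#' @param rho sparsity scale in `(0, 1]`.
#' @param seed RNG seed; the draw is deterministic given the seed.
#' @return A list of class `sbm_params`.
#' @export
sample_heterogeneous_params <- function(K_star, rho = 1, seed = 1L) {
  stopifnot(rho > 0, rho <= 1)
  theta <- with_seed(seed, {
    th <- matrix(0, K_star, K_star)
    diag(th) <- stats::runif(K_star, 0.5, 0.9)
    m <- K_star * (K_star - 1) / 2
    th[upper.tri(th)] <- stats::runif(m, 0.3, 0.5)
    th[lower.tri(th)] <- t(th)[lower.tri(th)]
    th * rho
  })
  structure(list(K_star = as.integer(K_star),
                 pi = rep(1 / K_star, K_star), theta_star = theta),
            class = "sbm_params")
}

# symmetric hollow Bernoulli adjacency given a node-level probability matrix
sample_adjacency <- function(P) {
  n <- nrow(P)
  A <- matrix(0L, n, n)
  up <- which(upper.tri(P))
  A[up] <- as.integer(stats::runif(length(up)) < P[up])
  A + t(A)
}

#' Simulate a stochastic block model graph
#'
#' Labels are drawn independently with the community probabilities `pi`
#' (so realized community sizes vary), then each unordered dyad connects
#' independently with the probability given by its pair of labels.
#'
#' @param params an `sbm_params`.
#' @param n number of nodes.
#' @param seed RNG seed; output is deterministic given
#'   `(params, n, seed)`.
#' @return A list with `graph` (`eb_graph`), `labels` (raw integer labels
#'   in `1..K_star`, possibly with empty communities) and `partition`
#'   (compacted `eb_partition` over the occupied communities).
#' @export
simulate_sbm <- function(params, n, seed = 1L) {
  stopifnot(inherits(params, "sbm_params"), n >= 2)
  with_seed(seed, {
    z <- sample.int(params$K_star, n, replace = TRUE, prob = params$pi)
    P <- params$theta_star[z, z, drop = FALSE]
    g <- eb_graph(sample_adjacency(P))
    list(graph = g, labels = z, partition = compact_partition(z))
  })
}

#' Simulate a graph from a graphon
#'
#' Latent positions `u_i ~ U(0, 1)` i.i.d.; each unordered dyad connects
#' independently with probability `W(u_i, u_j)`. The latent positions are
#' returned so oracle quantities can be evaluated.
#'
#' @param spec a [graphon_spec()].
#' @param n number of nodes.
#' @param seed RNG seed.
#' @return A list with `graph` (`eb_graph`) and `u` (latent positions).
#' @export
simulate_graphon <- function(spec, n, seed = 1L) {
  stopifnot(inherits(spec, "graphon_spec"), n >= 2)
  with_seed(seed, {
    u <- stats::runif(n)
    P <- outer(u, u, spec$W)
    list(graph = eb_graph(sample_adjacency(pmin(pmax(P, 0), 1))), u = u)
  })
}

# per-replicate stream seed derived from a master seed; stays below 2^31
replicate_seed <- function(seed, t) {
  (as.integer(seed) %% 1000003L) * 2011L + 7919L * as.integer(t)
}
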