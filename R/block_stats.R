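#' Per-block edge counts and dyad capacities
#'
#' Summarizes a graph under a partition into the sufficient statistics of
#' the blockwise Binomial model: the edge count of every block and its dyad
#' capacity. For communities `a != b` the capacity is `n_a * n_b`; a
#' diagonal block holds `n_a (n_a - 1) / 2` dyads since self loops are
#' excluded, so a singleton community has capacity 0.
#'
#' @param g an `eb_graph`.
#' @param z an `eb_partition` over the same nodes.
#' @return A list of class `block_stats` with `K`, `edge_counts` and
#'   `capacities`, both symmetric `K x K` integer matrices.
#' @export
block_counts <- function(g, z) {
  stopifnot(inherits(g, "eb_graph"), inherits(z, "eb_partition"))
  if (length(z$labels) != g$n)
    stop("partition covers ", length(z$labels), " nodes but graph has ", g$n)
  K <- z$K
  Zind <- matrix(0L, g$n, K)
  Zind[cbind(seq_len(g$n), z$labels)] <- 1L
  M <- t(Zind) %*% g$adjacency %*% Zind   # block sums over ordered pairs
  counts <- M
  diag(counts) <- diag(M) / 2
  counts[upper.tri(counts)] <- t(counts)[upper.tri(counts)]  # exact symmetry
  caps <- tcrossprod(z$sizes)
  diag(caps) <- z$sizes * (z$sizes - 1L) / 2
  storage.mode(counts) <- "integer"
  storage.mode(caps) <- "integer"
  structure(list(K = K, edge_counts = counts, capacities = caps),
            class = "block_stats")
}

#' @export
print.block_stats <- function(x, ...) {
  cat(sprintf("<block_stats> K = %d, %d edges over %d dyads\n", x$K,
              sum(x$edge_counts[upper.tri(x$edge_counts, diag = TRUE)]),
              sum(x$capacities[upper.tri(x$capacities, diag = TRUE)])))
  invisible(x)
}

new_connectivity_estimate <- function(theta, shrinkage, method) {
  structure(list(theta = theta, shrinkage = shrinkage, method = method),
            class = "connectivity_estimate")
}

#' @export
print.connectivity_estimate <- function(x, ...) {
  cat(sprintf("<connectivity_estimate> method = %s, K = %d\n",
              x$method, nrow(x$theta)))
  invisible(x)
}

#' Blockwise maximum likelihood connectivity estimate
#'
#' The empirical edge frequency of each block, `X^B_ab / n_ab`. Blocks with
#' zero dyad capacity (singleton diagonal blocks) get the value 0 by
#' convention, which keeps downstream squared-error metrics finite.
#'
#' @param stats a [block_counts()] result.
#' @return A `connectivity_estimate` with `method = "MLE"` and an all-zero
#'   shrinkage matrix.
#' @export
mle_theta <- function(stats) {
  stopifnot(inherits(stats, "block_stats"))
  theta <- ifelse(stats$capacities > 0L,
                  stats$edge_counts / pmax(stats$capacities, 1L), 0)
  new_connectivity_estimate(theta, shrinkage = theta * 0, method = "MLE")
}
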