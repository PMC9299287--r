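#' Specify a graphon
#'
#' A graphon is a symmetric function `W: [0,1]^2 -> [0,1]`; nodes receive
#' independent uniform latent positions and dyads connect independently
#' with probability `W(u_i, u_j)`. The built-in family
#' `W(x, y) = rho * lambda^2 * (x y)^(lambda - 1)` has mean density `rho`
#' (sparsity) and degree concentration controlled by `lambda`
#' (`lambda <= 1 / sqrt(rho)` keeps the function within `[0, 1]`).
#'
#' @param rho sparsity scale in `(0, 1]`.
#' @param lambda concentration parameter, `>= 1` and `<= 1/sqrt(rho)`.
#' @param W optional custom evaluator `function(x, y)`; overrides the
#'   built-in family (then `rho`/`lambda` are kept for metadata only).
#' @return A list of class `graphon_spec` with a vectorized evaluator `W`.
#' @export
graphon_spec <- function(rho = 0.1, lambda = 2, W = NULL) {
  if (is.null(W)) {
    if (rho <= 0 || rho > 1) stop("rho must lie in (0, 1]")
    if (lambda > 1 / sqrt(rho))
      stop("lambda must satisfy lambda <= 1/sqrt(rho)")
    W <- function(x, y) rho * lambda^2 * (x * y)^(lambda - 1)
  }
  structure(list(rho = rho, lambda = lambda, W = W), class = "graphon_spec")
}

#' Bin a latent position into a community interval
#'
#' With breakpoints `c_1 < ... < c_K = 1` (and implicit `c_0 = 0`), the bin
#' of `x` is `1 + sum_k I(c_k <= x)`: a point equal to a breakpoint falls
#' into the next bin.
#'
#' @param x numeric vector of positions in `[0, 1)`.
#' @param breakpoints increasing vector of upper endpoints, ending at 1.
#' @return Integer bin indices in `1..K`.
#' @export
bin_point <- function(x, breakpoints) {
  if (any(x < 0 | x >= 1)) stop("positions must lie in [0, 1)")
  # findInterval counts breakpoints <= x, matching the indicator convention
  1L + findInterval(x, breakpoints)
}

#' Relabel communities for graphon identifiability
#'
#' Graphons are identifiable only up to measure-preserving transformations;
#' the canonical representative makes the degree function
#' `g(l) = sum_k pi_k theta_{lk}` nondecreasing in `l`. Returns the stable
#' permutation achieving this (ties keep original order) and the permuted
#' proportions and connectivity.
#'
#' @param pi community proportions summing to 1.
#' @param theta symmetric `K x K` connectivity matrix.
#' @return A list with `perm`, `pi`, `theta` and the sorted degree
#'   function `g`.
#' @export
relabel_identifiable <- function(pi, theta) {
  stopifnot(abs(sum(pi) - 1) < 1e-8, nrow(theta) == length(pi))
  g <- as.vector(theta %*% pi)
  perm <- order(g)  # stable: ties keep original order
  list(perm = perm, pi = pi[perm], theta = theta[perm, perm, drop = FALSE],
       g = g[perm])
}

#' Piecewise-constant graphon estimate from a partition
#'
#' The unit interval is split into `K` pieces with lengths equal to the
#' community proportions `n_k / n`; the estimated graphon is constant on
#' each product of pieces, with the value given by the chosen connectivity
#' estimator (empirical Bayes by default). The canonical identifiability
#' relabeling is applied before the estimate is returned.
#'
#' @param g an `eb_graph`.
#' @param z an `eb_partition`.
#' @param method `"EB"` or `"MLE"`.
#' @param fit_cfg optimizer configuration for [fit_hyperparams()] (EB only).
#' @return A list of class `graphon_estimate` with `pi_hat`, `breakpoints`
#'   (length `K`, ending at 1), `theta` (relabeled), `method` and a
#'   vectorized evaluator `W(x, y)`.
#' @export
estimate_graphon <- function(g, z, method = c("EB", "MLE"), fit_cfg = list()) {
  method <- match.arg(method)
  stats <- block_counts(g, z)
  est <- switch(method,
                EB = eb_theta(stats, fit_hyperparams(stats, fit_cfg)$hyperparams),
                MLE = mle_theta(stats))
  pi_hat <- z$sizes / sum(z$sizes)
  rl <- relabel_identifiable(pi_hat, est$theta)
  breakpoints <- cumsum(rl$pi)
  breakpoints[length(breakpoints)] <- 1  # guard cumulative rounding
  theta <- rl$theta
  obj <- list(pi_hat = rl$pi, breakpoints = breakpoints, theta = theta,
              method = method,
              W = function(x, y) {
                theta[cbind(bin_point(x, breakpoints),
                            bin_point(y, breakpoints))]
              })
  class(obj) <- "graphon_estimate"
  obj
}

#' @export
print.graphon_estimate <- function(x, ...) {
  cat(sprintf("<graphon_estimate> %s, K = %d pieces\n",
              x$method, length(x$pi_hat)))
  invisible(x)
}

#' Evaluate a graphon estimate on a regular grid
#'
#' Dense evaluation of the piecewise-constant surface at cell midpoints,
#' suitable for export (e.g. `write.table`) or plotting with `image()`.
#'
#' @param est a [estimate_graphon()] result (or any object with a
#'   vectorized `W(x, y)`).
#' @param resolution grid points per axis.
#' @return A `resolution x resolution` matrix; rows/columns are named by
#'   the midpoint coordinates.
#' @export
graphon_grid <- function(est, resolution = 200L) {
  mid <- (seq_len(resolution) - 0.5) / resolution
  vals <- matrix(est$W(matrix(mid, resolution, resolution),
                       t(matrix(mid, resolution, resolution))),
                 resolution, resolution)
  dimnames(vals) <- list(format(mid, digits = 4), format(mid, digits = 4))
  vals
}

#' Integrated squared error between a graphon and an estimate
#'
#' The double integral of the squared difference over the unit square,
#' evaluated by the midpoint rule on a `resolution x resolution` grid. The
#' estimate is piecewise constant, so accuracy is limited only by the
#' smooth truth; grid midpoints falling exactly on a block breakpoint are
#' nudged by half a cell to keep the bin assignment unambiguous.
#'
#' @param truth a [graphon_spec()].
#' @param est a [estimate_graphon()] result (already relabeled) or any
#'   object with a vectorized `W(x, y)` evaluator.
#' @param resolution grid points per axis (>= 100).
#' @return The integrated squared error.
#' @export
graphon_mse <- function(truth, est, resolution = 500L) {
  stopifnot(inherits(truth, "graphon_spec"), resolution >= 100L)
  h <- 1 / resolution
  mid <- (seq_len(resolution) - 0.5) * h
  if (!is.null(est$breakpoints) &&
      any(abs(outer(mid, est$breakpoints, "-")) < 1e-12))
    mid <- mid - h / 4  # deterministic shift off the breakpoint
  gx <- matrix(mid, resolution, resolution)
  gy <- t(gx)
  d <- truth$W(gx, gy) - est$W(gx, gy)
  mean(d^2)
}
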