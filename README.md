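# ebsbm — empirical Bayes shrinkage and model selection for block models and graphons

Networks — protein interaction maps, regulatory circuits, social and
communication graphs — are routinely summarized by a stochastic block
model (SBM): nodes fall into `K` communities and each pair of communities
`(a, b)` has its own connection probability `θ_ab`. Once a clustering
algorithm has partitioned the nodes, the usual estimate of `θ_ab` is the
empirical edge frequency of the block, which becomes very noisy as soon as
`K` is large and blocks are small. `ebsbm` addresses both halves of that
problem for practitioners analyzing undirected simple graphs:

* **Shrinkage estimation.** A hierarchical Beta–Binomial model,
  `X^B_ab | θ_ab ~ Binomial(n_ab, θ_ab)` with
  `θ_ab ~ Beta(α_d, β_d)` (one prior for diagonal blocks, `d = 0`, one for
  off-diagonal blocks, `d = 1`), whose hyperparameters are fit by marginal
  maximum likelihood across all blocks. The resulting empirical Bayes
  estimate
  `θ̂_ab = (α_d + X^B_ab) / (α_d + β_d + n_ab)
        = η_ab · α_d/(α_d+β_d) + (1 − η_ab) · X^B_ab/n_ab`
  borrows strength across blocks through the shrinkage factor
  `η_ab = (α_d+β_d)/(α_d+β_d+n_ab)`.
* **Model selection.** A penalized joint marginal likelihood
  `J_Z − ½[(K−1) log n + K(K+1)/2 · log(n(n−1)/2)]` (ICL-style) scored on
  any set of candidate partitions picks the number of communities; the
  cluster-size cross-validation risk (CVRP) is computed alongside as a
  baseline.
* **Graphon estimation.** Any partition plus connectivity estimate yields
  a piecewise-constant graphon `Ŵ(x, y)` with the canonical
  (nondecreasing-degree) relabeling, plus integrated-squared-error metrics
  against a reference kernel.
* **Benchmark machinery.** Simulators for the standard dense/sparse,
  homogeneous/heterogeneous SBM designs and the graphon family
  `W(x,y) = ρλ²(xy)^(λ−1)`, a regularized spectral + EM-refined clustering
  front-end, and an experiment harness that aggregates selection
  frequencies and error curves over replicates.

Graphs load from whitespace edge lists (`load_edge_list`), MatrixMarket
pattern-symmetric adjacency files (`load_adjacency`/`save_adjacency`), and
two-column node-label TSVs (`load_labels`).

## Worked example

Simulate a 5-community affiliation network (within-community probability
0.9, between 0.1), score candidate partitions for `K = 1..8`, and compare
the shrinkage estimate with the blockwise MLE:

```r
library(ebsbm)

params <- make_homogeneous_params(K_star = 5, rho = 1, lambda = 0.9, eps = 0.1)
sim    <- simulate_sbm(params, n = 120, seed = 42)
sim$graph
#> <eb_graph> 120 nodes, 1857 edges, density 0.2601

parts <- candidate_partitions(sim$graph, cluster_config(k_range = 1:8, seed = 1))
sel   <- select_partition(sim$graph, parts)
score_table(sel$scores)
#>   K      J_Z   penalty    total      cvrp
#> 1 1 -4092.26   4.43673 -4096.69 -1.000000
#> 2 2 -3492.79  15.70395 -3508.50 -1.254624
#> 3 3 -3017.14  31.40790 -3048.55 -1.149835
#> 4 4 -2657.45  51.54858 -2709.00 -1.000420
#> 5 5 -2349.60  76.12599 -2425.73 -0.953957
#> 6 6 -2373.14 105.14014 -2478.28 -1.063403
#> 7 7 -2374.96 138.59103 -2513.55 -1.021176
#> 8 8 -2377.51 176.47865 -2553.99 -1.108310
sel$partition$K
#> [1] 5
```

The criterion total (`J_Z` minus the complexity penalty) peaks at the
planted `K = 5`. Fitting the hierarchical prior on the selected partition
and comparing estimates against the planted connectivity:

```r
st  <- block_counts(sim$graph, sel$partition)
fit <- fit_hyperparams(st)
fit
#> <eb_hyperparams> diagonal Beta(1e+06, 1.068e+05), off-diagonal Beta(1.133e+05, 1e+06)
#>   log-likelihood: diagonal -447.2817, off-diagonal -1884.6031

eb <- eb_theta(st, fit$hyperparams)
sbm_mse(mle_theta(st), sel$partition, params$theta_star, sim$labels)
#> [1] 6.92e-05
sbm_mse(eb, sel$partition, params$theta_star, sim$labels)
#> [1] 4.93e-06
```

Because this design gives every diagonal block the same true rate (and
likewise off-diagonal), the fitted priors run to high concentration — the
shrinkage factors approach 1 and blocks are pooled almost completely —
cutting the node-level mean squared error here from `6.9e-5` (MLE) to
`4.9e-6` (EB), a ratio of about 7%.

Command-line wrappers for batch work live in `inst/scripts/`
(`simulate.R` writes MatrixMarket + label + metadata files per replicate;
`experiment.R` runs a YAML-configured experiment and writes a JSON/TSV
report). The methods vignette
(`vignettes/hierarchical-block-models.Rmd`) documents the model,
numerical choices and limitations.

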