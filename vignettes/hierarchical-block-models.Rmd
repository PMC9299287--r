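---
title: "Empirical Bayes shrinkage and model selection for block models and graphons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical Bayes shrinkage and model selection for block models and graphons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

An undirected simple graph on $n$ nodes is recorded as a symmetric binary
adjacency matrix $X$ with an empty diagonal. Under a stochastic block model
(SBM), each node carries a latent community label $z_i \in \{1,\dots,K\}$
and each unordered dyad connects independently with probability
$\theta_{z_i z_j}$, where $\Theta = (\theta_{ab})$ is the $K \times K$
connectivity matrix. A graphon generalizes this: nodes receive uniform
latent positions $u_i \in [0,1]$ and dyads connect with probability
$W(u_i, u_j)$ for a symmetric kernel $W$; an SBM is exactly a piecewise
constant graphon.

Given a partition $Z$ of the nodes, block $(a,b)$ collects the dyads
between communities $a$ and $b$; it holds $n_{ab} = n_a n_b$ dyads for
$a \neq b$ and $n_{aa} = n_a (n_a - 1)/2$ within a community. Its edge
count is Binomial$(n_{ab}, \theta_{ab})$, so the per-block maximum
likelihood estimate is the empirical frequency
$\hat\theta^{\mathrm{MLE}}_{ab} = X^B_{ab} / n_{ab}$. When $K$ is large the
blocks are small and these frequencies are noisy — the motivation for
shrinkage.

`ebsbm` places a hierarchical Beta prior over the block connectivities:
$\theta_{aa} \sim \mathrm{Beta}(\alpha_0, \beta_0)$ for diagonal
(within-community) blocks and $\theta_{ab} \sim \mathrm{Beta}(\alpha_1,
\beta_1)$ for off-diagonal blocks. Two separate prior families respect the
assortative/disassortative asymmetry typical of real networks. The
posterior mean given the block count,
$$\hat\theta^{\mathrm{EB}}_{ab}
  = \frac{\alpha_d + X^B_{ab}}{\alpha_d + \beta_d + n_{ab}}
  = \eta_{ab}\,\frac{\alpha_d}{\alpha_d+\beta_d}
  + (1-\eta_{ab})\,\frac{X^B_{ab}}{n_{ab}},
\qquad
\eta_{ab} = \frac{\alpha_d+\beta_d}{\alpha_d+\beta_d+n_{ab}},$$
interpolates between the pooled prior mean and the block MLE. The
shrinkage weight $\eta_{ab}$ is 1 for empty blocks, decreases strictly
with block capacity, and is driven by the data through the fitted
hyperparameters: dispersed block rates give a diffuse prior (little
shrinkage), concentrated rates give a tight prior (strong pooling).

Hyperparameters are fit by marginal maximum likelihood. Integrating
$\theta_{ab}$ out of the configuration likelihood gives, per block,
$\log B(\alpha + x, \beta + n - x) - \log B(\alpha, \beta)$, summed over
the diagonal blocks for side $d = 0$ and the strict upper triangle for
$d = 1$; the two sides are maximized independently.

## Numerical choices in the fit

* All Beta-function arithmetic is in log space through `lgamma`/`lbeta`.
* Optimization runs in $(\log\alpha, \log\beta)$ with L-BFGS-B on the box
  $[\log 10^{-6}, \log 10^{6}]^2$, projected-gradient tolerance $10^{-8}$,
  and analytic digamma gradients. The log parameterization enforces
  positivity and conditions the ridge that appears when block rates are
  nearly equal: the marginal likelihood then increases without bound along
  growing concentration $\alpha + \beta$ (a degenerate point-mass prior),
  and the box caps that spike. Reported hyperparameters on such inputs sit
  on the box edge by design; the fitted likelihood value is what the
  selection criterion consumes, and it is insensitive to where the ridge
  is truncated.
* Starts: a method-of-moments fit to the blockwise rates, and always also
  the uniform prior $(1,1)$, keeping the better optimum — so the fitted
  likelihood can never fall below its value at $(1,1)$. Up to five seeded
  uniform restarts in the box are added if the optimizer reports
  non-convergence.
* A side with no informative block (the off-diagonal side when $K = 1$,
  or all-zero capacities) contributes exactly 0 and reports the neutral
  values $(1,1)$.

## Choosing the number of communities

Candidate partitions $Z_1, \dots, Z_m$ (one per trial $K$) are scored by a
penalized joint marginal likelihood. The goodness-of-fit term is
$$J_Z = \mathcal{L}(\hat\alpha_0, \hat\beta_0)
      + \mathcal{L}(\hat\alpha_1, \hat\beta_1)
      + \log m(Z),$$
where $m(Z)$ is the marginal mass of the partition under a symmetric
Dirichlet$(\tau)$ prior on the community proportions ($\tau = 1/2$, the
Jeffreys choice, by default). The selected partition maximizes
$$J_Z - \tfrac12\Big[(K-1)\log n + \tfrac{K(K+1)}{2}
      \log\tfrac{n(n-1)}{2}\Big],$$
an ICL-style penalty charging half a $\log$-sample-size per free
proportion and per free connectivity. Ties break toward the smallest
realized $K$. The cluster-size cross-validation risk (CVRP)
$\mathcal{J}(K) = 2K/(n-1) - (n+1)K/(n-1)\sum_i (n_i/n)^2$ is computed
alongside as a baseline.

**The form of $m(Z)$ is a deliberate design decision.** Marginalizing a
Dirichlet prior against the *specific* label vector gives
$\Gamma(K\tau)\prod_i\Gamma(n_i+\tau) /
\big(\Gamma(n+K\tau)\prod_i\Gamma(\tau)\big)$, which charges the full
assignment entropy $\approx n H(\hat\pi) \approx n \log K$ against every
multi-community model. On weakly separated networks that term dominates
any achievable likelihood gain — even scoring the *true* partition of a
sparse benchmark graph loses to $K = 1$ — so a criterion built on it
degenerates to selecting one community, which is not how this family of
criteria behaves in practice. The default therefore uses the exchangeable
form: the mass of the community *size vector*, i.e. the assignment mass
times the multinomial coefficient $\binom{n}{n_1 \cdots n_K}$, an
$O(K \log n)$ quantity that acts as a mild additional penalty. The literal
assignment mass remains available
(`dirichlet_logmass(..., assignment = TRUE)`,
`select_config(partition_prior = "assignment")`) and retains its defining
property that the masses over all $K^n$ label vectors sum to one, which
the test suite verifies by enumeration.

## Partitions: spectral front-end with likelihood refinement

The scoring machinery accepts any partition. The built-in front-end is
regularized spectral clustering: the adjacency is lifted by
$\tau_{\mathrm{reg}} \bar d / n$ on every dyad (default
$\tau_{\mathrm{reg}} = 1$, which also absorbs isolated nodes), normalized
symmetrically by degrees, and the row-normalized top-$k$ eigenvectors are
clustered by k-means with 20 seeded restarts. On top of the k-means
labels, a mean-field EM pass on the block-model likelihood (point
estimates for proportions and connectivities, lightly smoothed) polishes
the assignment; the best of a few perturbation restarts by complete-data
likelihood is kept, and communities emptied by the polish are compacted
away.

The refinement step matters: some benchmark designs (notably the dense
heterogeneous one) place the community signal below the spectral
detectability edge — the informative eigenvalues sit inside the noise
bulk — where embeddings alone recover only coarse structure while
likelihood ascent still improves it materially. Refinement never degrades
the complete-data likelihood of the labels it is given, and with
`refine = FALSE` in `cluster_config()` the front-end reduces to plain
spectral clustering. Everything is deterministic given the configuration
seed.

## Graphon estimation

A partition plus a connectivity estimate define a piecewise-constant
graphon: the unit interval is split into pieces of length $n_k/n$ and
$\hat W(x,y)$ is the estimated connectivity of the pair of pieces
containing $(x,y)$, with the boundary convention that a point equal to a
breakpoint belongs to the next piece. Because graphons are identifiable
only up to measure-preserving maps, communities are relabeled so the
degree function $g(l) = \sum_k \hat\pi_k \hat\theta_{lk}$ is nondecreasing
(stable sort; ties keep their order); the built-in benchmark family
$W(x,y) = \rho\lambda^2 (xy)^{\lambda-1}$ already satisfies the constraint
for $\lambda \ge 1$, so only estimates are relabeled before comparison.
The integrated squared error against a reference kernel is computed by the
midpoint rule on a 500-point-per-axis grid by default: the estimate is
piecewise constant, so accuracy is limited by the smooth reference only,
and a refinement check (200 vs 800 points) bounds the grid error; grid
midpoints colliding with a breakpoint are nudged deterministically by a
quarter cell.

## The simulators and what they emulate

The generator reproduces the benchmark designs the estimators are
evaluated on, with the study's published parameter values as defaults:

* **Dense homogeneous (model 1)** — planted affiliation matrix with
  $\rho\lambda = 0.9$ on the diagonal and $\rho\varepsilon = 0.1$ off it,
  $K^* = 10$, $n = 200$; expected density
  $\rho(\lambda/K^* + \varepsilon(1 - 1/K^*)) = 0.18$.
* **Sparse homogeneous (model 2)** — the same matrix scaled by
  $\rho = 0.2$ (density $\approx 0.036$), sizes up to $n = 450$.
* **Heterogeneous (models 1s/2s)** — per-network diagonal entries drawn
  from $U(0.5, 0.9)$ and off-diagonal entries from $U(0.3, 0.5)$ (drawn on
  the upper triangle and mirrored, since the graph is undirected), scaled
  by $\rho$.
* **Graphon (models 3/4)** — $W(x,y) = \rho\lambda^2(xy)^{\lambda-1}$ at
  $n = 100$ and $n = 316$, $\rho \in \{10^{-1}, 10^{-1.5}, 10^{-2}\}$,
  $\lambda \in \{2,3,5\}$; mean density $\rho$.

Labels are multinomial with equal probabilities, so realized community
sizes vary — no balancing is applied. Each replicate derives its own RNG
stream from the master seed, making full experiments reproducible and
parallelizable. What the simulators do *not* emulate: degree
heterogeneity within communities (no degree correction), weighted or
directed edges, and dependence between dyads. Passing benchmarks here
therefore speaks to exchangeable-graph regimes, not to networks with hub
structure.

## Evaluation metrics

Connectivity estimates are compared at the node level
($\Theta'_{ij} = \theta_{Z(i)Z(j)}$ expanded through each estimate's own
partition, making label switching irrelevant), averaging squared errors
over ordered off-diagonal pairs. Graphon estimates are compared by the
integrated squared error after identifiability relabeling. For a candidate
range of $K$, $\tilde K$ denotes the $K$ minimizing the *MLE's* error —
by definition, even when the reported estimator is EB — and selection
quality is summarized by mean absolute deviations of the selected
$\hat K$ from $K^*$ and from $\tilde K$. A held-out dyad log-likelihood
(seeded node split, estimates fit on the observed subgraph) supports
comparisons on graphs without ground truth.

## Problem sizes and runtime

The bundled experiment defaults are desk-scale choices: 20–50 replicates
per design, candidate $K$ up to 20, and error-integral resolution 200 in
experiment loops (500 in one-off computations). One dense $n = 200$
replicate scores all 20 candidates in well under a second; the sparse
$n = 450$ design takes a few seconds per replicate, dominated by the EM
polish. The Monte-Carlo summaries are stochastic; deviation metrics at
these replication levels carry standard errors of roughly 0.1–0.2 blocks.

## Known limitations

* Selection quality inherits the candidate partitions. The spectral+EM
  front-end matches likelihood-based clustering on homogeneous designs but
  remains weaker on the dense heterogeneous design, where the signal lies
  below the spectral edge; deviation summaries there are larger than what
  a fully likelihood-based candidate ensemble can attain.
* The marginal likelihood is not concave; the box and restart scheme make
  the fit reproducible, but global optimality on pathological inputs is
  not guaranteed.
* No degree-corrected variant, no directed/weighted graphs, and no
  smooth (model-averaged) graphon estimates — the estimate is piecewise
  constant by construction.
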