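# rsbm

Community detection in undirected multigraphs with a **regularized
stochastic block model** (RSBM): a single prior parameter steers
maximum-likelihood partition inference toward assortative communities or
disassortative (core–periphery, bipartite-like) structure.

## The problem and the model

Stochastic block models place edges between nodes according to their latent
block labels `g`. Their likelihoods fit assortative and disassortative
partitions equally well, so on networks with weak community signal,
MCMC inference under the degree-corrected SBM converges to whichever local
optimum its starting point falls toward — often a disassortative one even
when communities are sought.

The RSBM gives every node two Poisson rate factors, `I_i` for within-block
edge endpoints and `O_i` for cross-block ones
(`λ_ij = ω_{g_i g_j} I_i I_j` within a block, `ω_{g_i g_j} O_i O_j`
across). With the block-pair rates `ω` profiled out, the log-likelihood is

    L(A | g, I, O) = Σ_rs m_rs log( m_rs / Λ_rs )
                     + 2 Σ_i ( k_i⁺ log I_i + k_i⁻ log O_i )

with `Λ_rr = (Σ_{i∈r} I_i)²` and `Λ_rs = Σ_{i∈r} O_i · Σ_{j∈s} O_j`.
Setting `I = O = 1` recovers the standard SBM, `I = O = k` the
degree-corrected SBM. Writing `f_i = I_i/(I_i+O_i)` and
`θ_i = I_i + O_i` turns the second sum into `−2 Σ_i k_i H(k_i⁺/k_i, f_i)`
plus a constant, where `H` is a cross entropy: maximizing the likelihood
pulls each node's observed in-degree ratio `k_i⁺/k_i` toward the **prior
in-degree ratio** `f_i`. The default prior is `f_i = max(f, 1/k_i)` with
`θ_i = k_i`: one knob `f` — near 1 for communities, near 0 for
core–periphery.

The package provides the likelihood family (`rsbm_loglik`,
`prior_spec`), single-move MCMC over partitions with exact handling of the
`f(1)=1` hard constraints (`mcmc_run`, `multi_restart`,
`exhaustive_search`), a planted-partition benchmark generator with
power-law degrees (`sample_dcsbm`, `benchmark_instance`), coverage and
modularity metrics (`coverage`, `modularity_score`, `match_partitions`),
and experiment drivers (`run_convergence_trials`, `run_sparsity_sweep`,
`run_f_sweep`). A thin command-line wrapper lives in
`inst/cli/rsbm-cli.R`.

## A worked example

Generate the 20-node planted-partition benchmark (two blocks of 10,
power-law degrees with exponent 2.5, within-block rate 10× the
between-block rate) and fit both models with 20 MCMC restarts:

```r
library(rsbm)

bench <- benchmark_instance(seed = 1)   # first admissible draw (seed 23)
fit <- rsbm(bench$graph, B = 2, model = "rsbm", f = 0.8,
            restarts = 20, seed = 101, reference = bench$partition)
fit
#> Stochastic block model fit (20 MCMC restarts)
#> Prior spec: RSBM, f_i = max(0.8, 1/k_i), theta_i = k_i
#>   blocks: 2 (sizes: 10, 10)
#>   log-likelihood: 27.3693
#>   coverage: 0.9091, modularity: 0.3976
#>   restarts matching reference: 19 / 20
```

19 of 20 independent restarts converge to the planted partition (the
remaining trial lands in a nearby local optimum), with coverage 0.91 —
most edges inside blocks — and two-block modularity 0.40. The fitted
block-pair rate matrix `coef(fit)` has a dominant diagonal, and
`summary(fit)` lists the per-trial log-likelihoods, the step at which each
trial first reached the planted partition (median well under 150
proposals), and the matched flag. Under `model = "dcsbm"` on the same graph
the restarts are not steered: which optimum each trial reaches depends on
its starting point.

On a real network, sweeping the floor `f` reproduces the structure
switch:

```r
G <- read_edge_list(system.file("extdata", "karate.edgelist", package = "rsbm"))
rsbm(G, B = 2, f = 0.14, seed = 1)$coverage   # core-periphery: 0.28
rsbm(G, B = 2, f = 0.85, seed = 1)$coverage   # assortative:    0.87
```

At `f = 0.85` the inferred split is the network's classical two-faction
partition up to a single degree-2 node with one edge to each faction.

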