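---
title: "Modeling gene expression evolution across a species phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling gene expression evolution across a species phylogeny}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(expevo)
```

## The question and the models

Given replicated expression measurements (log2 FPKM) for orthologous genes in
a handful of species with a known time-calibrated phylogeny, which
evolutionary force shaped each gene's expression level — drift, stabilizing
selection, or a branch-specific (directional) change? `expevo` answers this
per gene by Bayesian comparison of six models of how the *species-mean*
expression level evolves, all sharing a within-species observation layer:
individual replicate $X_{ij}$ of species $j$ is
$\mathrm{Normal}(\mu_j, \delta^2_j)$, with one free within-species variance
$\delta^2_j$ per species. Treating $\delta^2_j$ as species-specific is
justified empirically: per-gene expression variances are heterogeneous and
essentially uncorrelated between species
(`variance_correlation_matrix()`; `analysis/02_variance_structure.R`).

The six models differ in how the species means $\mu_j$ arise:

1. **EQUAL_MEANS** — one global mean $\mu$; no evolution (fully conserved).
2. **UNEQUAL_MEANS** — independent per-species means $\mu_j$; differences
   without any phylogenetic mechanism.
3. **BM** — Brownian drift along the tree with rate $\sigma^2$
   (log2² · MY⁻¹); the tip means are multivariate normal with covariance
   given by shared branch lengths.
4. **BM_SHIFT** — drift with one *foreground* branch carrying its own rate
   $\sigma^2_F$ against the background $\sigma^2_B$; an elevated foreground
   rate is the drift-framework signature of directional selection.
5. **OU** — Ornstein–Uhlenbeck: drift $\sigma^2$ plus attraction of strength
   $\alpha$ (MY⁻¹) toward an optimum $\theta$ (log2 units); stationary
   variance $\sigma^2/(2\alpha)$, the model of stabilizing selection.
6. **OU_SHIFT** — OU with a foreground-branch rate *and* optimum
   ($\sigma^2_F$, $\theta_F$) differing from the background
   ($\sigma^2_B$, $\theta_B$), with a single shared $\alpha$ — five free
   parameters beyond the $\delta^2_j$ nuisances.

For the phylogenetic models the latent species means are integrated out
analytically: the species sample means are jointly multivariate normal with
the model's phylogenetic covariance plus $\delta^2_j/n_j$ on the diagonal,
and the within-species scatter factors out. Everything reduces to cheap
5×5 linear algebra, implemented once in compiled code.

### Root treatment

The BM-family likelihood is computed by REML — the likelihood of contrasts,
i.e. of linear combinations orthogonal to the grand mean — so the unobservable
root state is never a parameter and the likelihood is invariant to adding a
constant to all observations. Our contrast basis is orthonormal in the space
of *individual* observations (within-species contrasts plus
replicate-weighted between-species contrasts), which makes the species-level
formula exactly equal to a brute-force contrast density over the full
per-individual covariance matrix, with no basis-dependent constant.

An OU model with an attracting optimum is not translation-invariant, so REML
does not apply; instead the root mean is drawn from the OU stationary
distribution $\mathrm{Normal}(\theta, \sigma^2/(2\alpha))$. This choice makes
the tip variance exactly $\sigma^2/(2\alpha)$ — time-independent — and the
covariance between two tips $(\sigma^2/2\alpha)\,e^{-\alpha d_{ij}}$ with
$d_{ij}$ the tree distance. One consequence worth stating: as
$\alpha \to 0$ the *raw* stationary covariance diverges like $1/2\alpha$, so
the Brownian limit holds for the estimable, mean-centered structure — all
pairwise difference variances $2v(1 - e^{-\alpha d_{ij}}) \to \sigma^2
d_{ij}$ — not for raw covariance entries. The package therefore checks the
limit on the double-centered covariance, where agreement at
$\alpha = 10^{-8}$ is at the $10^{-7}$ level, and `ou_tip_moments()` refuses
$\alpha < 10^{-12}$ rather than overflow (use `bm_tip_covariance()` for the
limit). Branch-variance terms use `expm1` so $(1-e^{-2\alpha t})/(2\alpha)$
stays accurate for small $\alpha t$.

## Priors, MCMC and model selection

Priors follow the study protocol: means and optima are Uniform(−20, 20) in
log2 units; $\sigma^2$ (all variants), $\alpha$ and the $\delta^2_j$ are
log-uniform(1e−5, 1e5). The sampler is Metropolis–Hastings with
sliding-window proposals reflecting at the prior bounds — on the natural
scale for interval-bounded parameters, on the log scale (a multiplicative
proposal) for positive ones, where the log-uniform prior is flat. Each
parameter is updated twice per iteration in random order. The default
schedule is the study's: 2000 burn-in iterations with auto-tuning every 100
toward a 0.44 per-proposal acceptance rate, then 50,000 iterations thinned by
10 (5000 retained samples). Tuning is frozen after burn-in so the main chain
is a valid Markov chain; runs are bit-reproducible given the seed. By default
all parameters initialize from their priors (with a bounded number of
retries until the likelihood is finite); `init_at_mean = TRUE` pins
means/optima at the grand sample mean to shorten burn-in.

Marginal likelihoods come from stepping-stone sampling: powers
$\beta_k = \mathrm{qbeta}(k/K, 0.3, 1)$, $k = 1..K$ (default $K = 128$,
concentrating stones near $\beta = 0$ where the integrand moves fastest);
$K$ chains run at powers $\{0, \beta_1, \dots, \beta_{K-1}\}$, each
warm-started from the previous stone, and the per-stone importance ratios are
combined in log space. A model with every parameter held fixed integrates
over an empty space, so its log marginal is its log likelihood — a useful
exactness check. Model probabilities use equal prior model weights;
`prob_to_bf()` maps a two-model probability $p$ to the Bayes factor
$p/(1-p)$, so 0.75 ↔ 3 ("positive") and 0.95 ↔ 19 ("strong"). Thresholds are
applied on model probability, not on rounded Bayes factors.

## The decision procedures

**Phylogenetic signal** (`test_phylo_signal()`): BM against each
non-phylogenetic model, and the two non-phylogenetic models against each
other. Note a structural asymmetry we verified by exact quadrature of the
marginals: with five species, one free rate, and translation-invariant
contrasts, BM can absorb almost any mean pattern at a large enough
$\sigma^2$, while UNEQUAL_MEANS pays five prior penalties — so even
deliberately anti-phylogenetic patterns (sister species pushed far apart,
distant species equal) only *erode* BM's support below the positive
threshold rather than reversing it. Tests assert that directional statement.

**Conserved genes** (`conserved_gene_test()`): marginal likelihoods are
prior-sensitive, so conservation ($\sigma^2 = 0$) is tested by Monte Carlo
instead: fit the EQUAL_MEANS posterior (global mean plus the $\delta^2_j$),
draw `n_sim` posterior parameter vectors (default 1000), simulate one data
set per draw with the gene's replicate layout, estimate the posterior-mean
BM $\sigma^2$ for each simulated set and for the real gene, and flag the
gene conserved iff its value does not exceed the 95th percentile of the
simulated ones. By exchangeability the nominal size is ≈5%; the calibration
experiment (200 repetitions with shortened chains, `n_sim = 100`) checks the
conserved rate on $\sigma^2 = 0$ genes against 0.95. Screening $G$ genes
costs $G(n_{\mathrm{sim}}+1)$ MCMC analyses (`conserved_test_workload()`).

**Branch shifts** (`branch_shift_test()`): one tip at a time, shift model vs
its base model, significance at model probability > 0.75 (0.95 available via
`threshold`). No multiple-testing correction is applied across tips or genes
— support is reported per comparison, Bayes-factor style. Direction for BM
shifts uses sample means (BM has no optimum): sign of the foreground mean
minus the mean of background species means; OU shifts use the posterior mean
of $\theta_F - \theta_B$; exact zeros break toward "down" with a tie flag.
Follow-ups: `sign_test()` (exact two-sided binomial on the up/down split) and
`variance_shift_comparison()` (two-sided Wilcoxon rank-sum on per-gene
variances).

A power caveat we quantified (stepping-stone estimates agree with exact
quadrature to ~0.01 log units, so this is the method, not the estimator): a
single-tip rate shift of ratio 20 carries about one degree of freedom of
evidence; against the Occam penalty of a 10-decade log-uniform rate prior,
per-gene detection power at the BF > 3 threshold is only ~1/3 on the
5-species tree, insensitive to the background-rate scale, replicate counts
and $\delta^2$. False positives on plain-drift genes stay at a few percent.
This matches the general warning that small phylogenies support only weak
inference about branch-specific processes.

## Divergence analytics and the OU bias study

Under drift, the expression difference of two species separated by time $T$
is $\mathrm{Normal}(0, 2\sigma^2 T)$; folding it at zero gives the expected
absolute divergence $2\sigma\sqrt{T/\pi}$ (`expected_abs_divergence_bm()`).
`divergence_curve()` simulates species means for many genes (default 10,000)
along the tree and overlays that expectation — for OU the stationary
difference variance $2\,\frac{\sigma^2}{2\alpha}(1-e^{-\alpha d})$, which
flattens with depth as $\alpha$ grows. `estimate_sigma2_ss()` is the
companion moment estimator: per gene the mean over species pairs of
$(\bar x_i - \bar x_j)^2 / (2 T_{ij})$, unbiased under drift.

`ou_bias_study()` quantifies why OU fits on small trees mislead: for each
(taxa, $\sigma$, $\alpha$) cell it simulates pure-birth (Yule) trees rescaled
to unit root height — the paper-independent neutral choice, since tree shape
is not the manipulated variable — draws one stationary-OU value per tip, and
fits ($\alpha$, $\sigma^2$, $\theta$) by profile maximum likelihood
(1-D optimization over $\log\alpha$ with GLS mean and profiled variance; ML
rather than per-replicate MCMC keeps 1000-replicate grids tractable and
isolates the likelihood-surface pathology itself; failed fits are dropped
and counted, never imputed). Relative bias is
$(\overline{\hat\alpha} - \alpha)/\alpha$. The qualitative result is robust:
enormous positive bias at 5–10 taxa, collapsing around 50 taxa, with the
sampling spread shrinking alongside.

## The synthetic data generator

`generate_dataset()` stands in for the study's real transcriptome data. Its
defaults mirror the study design: the 5-taxon tree from `fixture_tree()`
(root height 11.8 MY, youngest split 5.5 MY; the two internal node ages not
fixed by those endpoints default to 8.7 and 9.0 MY, grouping erato with
(sara, charithonia) against (doris, melpomene) — all configurable);
per-species replicate totals 12, 11, 6, 12, 8 (paired-sex layout, 49
samples; sex is encoded in sample names but not modeled, matching the pooled
analysis); and a regime mixture of 3% conserved, 81% drift, 16% tip shifts
(the OU share defaults to zero and is configurable). Drift rates are drawn
log-uniformly on [0.05, 5] (within the ~0–9 range the sum-of-squares
estimator reports on such data), root/global means uniformly on [1, 9] log2
FPKM, and within-species variances log-normal(log 0.3, 0.7) **independently
per gene and species** — heterogeneous and uncorrelated across species,
which is the premise the variance-heterogeneity check tests. Directional
shifts are a drift background plus a signed offset of 2–5 log2 units on one
uniformly chosen foreground tip, so the ground-truth direction is
well-defined for calibration.

What the generator deliberately does not emulate: count-level measurement
noise and FPKM normalization artifacts, sex-biased expression, correlated
variance structure between species, missing species per gene, and
orthology-assignment error. Passing tests therefore demonstrate correctness
and calibration of the *methods* under the model's own assumptions, not
robustness of the biological conclusions to these real-data complications.

## Numerical and testing choices

* Ultrametricity is required within a relative tolerance of 1e-6 of root
  height and never auto-corrected; missing branch lengths are an error.
* The expressed-everywhere filter keeps a gene iff FPKM > 0 in every sample;
  log2 is applied with no pseudocount (zeros cannot reach the filter).
* Sample variances use the unbiased $n-1$ denominator; a species with a
  constant per-gene variance vector yields `NA` correlations, never 0.
* Non-positive-definite assembled covariances reject the proposal inside the
  sampler and raise an error naming the parameters at the user surface.
* Degenerate data (all replicates identical) are handled: the drift-rate
  posterior piles onto its lower prior bound.
* Test and acceptance problem sizes are scaled to keep the full suite within
  minutes while leaving Monte-Carlo margins of 3 standard errors: e.g. 25–100
  random draws for oracle equivalence, 3000–10,000 simulated genes for
  moment checks, 200 repetitions for conserved-test calibration, 30 + 50
  genes for shift recovery and false positives, and 200 replicates per cell
  at 5 vs 100 taxa for the bias study. Simulation experiments use shortened
  chains (hundreds of iterations) after verifying on conjugate and
  quadrature oracles that the estimates they feed are accurate at that
  length.

## Known limitations

Single foreground branch per fit (tip branches in the study design; internal
branches are accepted by the interface); single shared $\alpha$ in OU_SHIFT;
no multi-regime OU; no cross-gene hierarchical pooling; no multiple-testing
control beyond Bayes-factor reporting; OU parameters on 5 taxa are close to
unidentifiable (that is, quantitatively, what the bias study shows), so OU
shift calls should be read as model comparison outcomes, not parameter
estimates.
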