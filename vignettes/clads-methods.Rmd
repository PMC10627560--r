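---
title: "Data-augmented inference under the ClaDS diversification model"
author: "cladsmc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-augmented inference under the ClaDS diversification model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The cladogenetic diversification rate shift (ClaDS) process is a birth–death
model in which every edge of the phylogeny carries its own birth rate
$\lambda$ and death rate $\mu$. The process starts at the crown with an
initial birth rate $\lambda_0$. At every birth event the two daughter
lineages draw new birth rates from a lognormal inheritance kernel,

$$\lambda_1, \lambda_2 \sim \mathrm{LogNormal}\!\big(\log(\alpha_\lambda
\lambda_N),\ \sigma_\lambda\big),$$

where $\lambda_N$ is the parent's rate, $\alpha_\lambda > 0$ is a trend
parameter (values below 1 shrink rates toward the tips, above 1 inflate
them) and $\sigma_\lambda \ge 0$ controls the size of the shifts. The model
is designed for small progressive rate changes rather than rare large
shifts. A useful summary is the mean rate variation at branching,
$m_\lambda = \alpha_\lambda \exp(\sigma_\lambda^2/2)$, the expected
multiplicative change in rate across a speciation event
(`mean_rate_variation()`).

Death rates follow one of three modes:

* **turnover** — $\mu = \epsilon \lambda$ on every lineage, with a single
  turnover parameter $\epsilon$ (the ClaDS2-style parametrisation);
* **lognormal** — $\mu$ inherited like $\lambda$ with its own
  $(\mu_0, \alpha_\mu, \sigma_\mu)$;
* **none** — pure birth ($\mu = 0$, ClaDS0).

Each extant species is sampled at the present independently with
probability $\rho$. Not all parameters are jointly identifiable: at least
one of $\rho$, $\lambda_0$, and the death anchor ($\epsilon$ or $\mu_0$)
must be held fixed; the constructor `clads_params()` enforces this.

## Data augmentation

The likelihood of a reconstructed tree under ClaDS has no closed form.
Instead of integrating the hidden part of the process numerically, the
sampler works on the *complete* tree: the Markov chain explores the joint
space of the reconstructed tree, the scalar parameters, and an augmentation
that attaches to every reconstructed edge a complete subtree containing the
edge itself (the *spine*) and all extinct or unsampled lineages branching
from it. The joint density of a complete tree factorises into elementary
terms — exponential survival factors $e^{-(\lambda_i+\mu_i)t_i}$ for every
constant-rate lineage segment, a rate factor $\lambda$ ($\mu$) for every
birth (death) event, the lognormal inheritance densities of the daughter
rates at every birth, and $\rho$ / $(1-\rho)$ factors for sampled and
unsampled extant tips — and is computed by `complete_tree_log_density()`.

Two conventions deserve mention because the literature leaves them open:

* **Crown start.** The process starts at the crown split with rate
  $\lambda_0$; the two crown edges draw their rates from
  $(\lambda_0, \mu_0)$ through the ordinary inheritance kernel, and no
  $\lambda_0$ rate factor is charged for the crown split itself. Stem
  edges are not supported. Any fixed convention used consistently by the
  sampler and the forward simulator yields a self-consistent model; the
  sampling-from-prior harness (below) checks exactly that consistency.
* **$\sigma = 0$.** Deterministic inheritance is treated as a hard
  constraint (daughter rate exactly $\alpha$ times the parent rate within
  a $10^{-12}$ relative tolerance), never as a degenerate density.

## Subtree simulation and proposals

Augmented subtrees are proposed by exact Gillespie simulation
(`simulate_subtree()`): one seed lineage whose rates are drawn from the
ancestral rates, exponential waiting times at the summed lineage rates,
uniform choice of a spine among the survivors at the edge end, and
continued simulation of the remaining survivors until extinction or the
present. A simulation is *invalid* — and the whole Metropolis–Hastings
proposal auto-rejected — if the subtree dies before the edge end, if a
hidden lineage survives to the present and is flagged sampled, or if the
event cap is exceeded. The proposal's exact log-density `log_q` is
accumulated during simulation and can be recomputed from the stored record
(`subtree_proposal_log_density()`); the two computations follow different
factorisations of the same product and agreeing to $10^{-9}$ is one of the
package's standing cross-checks. The spine tip of an edge that ends at the
present is the reconstructed (sampled) tip itself; it is therefore not
given a Bernoulli sampling flag during simulation and contributes no
$\rho$ factor to `log_q` — the factor would cancel in every Hastings ratio
because old and new subtree belong to the same edge.

Tree moves are augmented versions of the standard reconstructed-tree
operators: Wilson–Balding prune-and-regraft, narrow subtree exchange, and
node (age) shift. Each resimulates only the subtrees of the edges it
touches — at most the edge above the moved node and the two edges below it
for a node shift — and adds $\log q(\text{old}) - \log q(\text{new})$ per
resimulated edge to the Hastings ratio. A fourth operator resimulates the
subtree of one uniformly chosen edge without touching the reconstructed
tree. Scalar-parameter moves never resample subtrees.

## Mixing: non-centered updates

The centered parameterisation couples $\sigma_\lambda$ and
$\alpha_\lambda$ tightly to the latent rate draws, which makes plain scale
moves mix very slowly (the well-known pathology of augmented samplers; the
original implementation reports augmented-operator acceptance around 0.03).
The engine therefore stores, for every latent rate draw, a link to the draw
that produced its parent lineage, which makes the standardized deviations
$z = (\log\lambda_c - \log(\alpha_\lambda\lambda_p))/\sigma_\lambda$
reconstructible. Three additional update types exploit this:

* joint scale moves on $\lambda_0$, $\alpha_\lambda$ or $\sigma_\lambda$
  that deterministically recompute every latent rate keeping its $z$ fixed
  (with the triangular log-scale Jacobian in the Hastings ratio);
* "prior kick" independence proposals that cross posterior tails in one
  jump;
* slice-sampling updates (stepping-out and shrinkage on the log scale)
  along the same non-centered direction, which draw from the exact
  conditional and need no tuning;
* centered slice updates of $\alpha_\lambda$ and $\sigma_\lambda$
  through the inheritance sufficient statistics (count, sum and sum of
  squares of the log-deviations), the other half of an interweaving
  (ASIS) sandwich, with O(1) slice evaluations;
* slice updates of single edge seed rates (exact 1-D conditionals,
  touching only the dependent edge contributions);
* elliptical slice sampling of the entire standardized-deviation field
  (its prior is exactly N(0, I)), which relaxes the aggregate latent
  summaries that otherwise pin $\sigma_\lambda$.

All of these leave the target invariant; they are validated against an
independently written fixed-tree sampler in the test suite and by the
sampling-from-prior harness together with everything else.

## Sampling-from-prior validation

Running the MCMC without data makes the chain target the tree prior
itself. `prior_sampling_validation()` compares that chain against plain
forward simulation under the same priors: parameters drawn from the
priors, complete trees simulated at the fixed crown age, and replicates
kept only if they have exactly `n_taxa` sampled tips *and* both crown
lineages have sampled descendants (so the reconstructed root age equals
the crown age the chain holds fixed — without this second condition the
two paths target different distributions). Four statistics are compared by
two-sample Kolmogorov–Smirnov tests with Bonferroni correction: the gamma
statistic, the Colless index, the branch-length-weighted mean birth rate
over the reconstructed tree, and $\sigma_\lambda$.

Because the logged chain is autocorrelated and the KS test assumes
independent draws, the harness subsamples the MCMC side at an interval
calibrated to three times the integrated autocorrelation time, estimated
as a rank-based effective sample size (rank-based because KS is a rank
test). The forward side is independent by construction and enters at full
size; the two-sample test is valid for unequal sample sizes. The report
prints both sizes alongside the KS table.

Default harness conditions, chosen once: 10 taxa, crown age 10 (so the
prior-predictive median richness, with $\lambda_0$'s prior median of 0.1,
is of the same order as the conditioning), $\rho$ fixed at 0.9 — a
realistic incomplete-sampling setting that, unlike $\rho = 1$, exercises
the $(1-\rho)$ tip factors and the hidden-survivor code paths on both
paths. The harness uses its own weakly informative priors
(`validation_priors()`), identical on both paths:
$\lambda_0 \sim \mathrm{LogNormal}(\log 0.1, 0.75)$,
$\alpha_\lambda \sim \mathrm{LogNormal}(0, 0.4)$,
$\sigma_\lambda \sim \mathrm{Exponential}(0.7)$,
$\epsilon \sim \mathrm{Uniform}(0, 1)$; they put less mass than the
inference defaults on strongly supercritical regimes whose complete trees
are enormous — scientifically uninteresting for a ten-tip comparison and
computationally dominant.

```{r}
library(cladsmc)
check <- prior_sampling_validation(n_taxa = 10, root_age = 10,
                                   n_samples = 5000, seed = 1)
print(check)
plot(check)
```

The packaged test suite runs this harness at a reduced scale (1,000
logged samples per path) so the whole suite stays within a desk-scale
runtime; `cmd_validate()` runs the full 5,000-sample version.

## Numerical choices and guards

* **Event caps.** Subtree simulations are capped at 1,000 Gillespie
  events and forward simulations at 5,000 events and a configurable
  number of coexisting lineages. The vague priors put some mass on
  strongly supercritical regimes whose complete trees are astronomically
  large; capped simulations count as invalid proposals / rejected
  replicates on *both* validation paths. The probability that a capped
  realization would have produced a small conditioned tree is negligible,
  so the truncation is far below the resolution of the distribution
  comparisons.
* **Degenerate edges.** Zero-duration edges (possible at proposal
  boundaries) are proposal-invalid rather than special-cased in the
  densities.
* **Stale proposal densities.** Cached subtree `log_q` values are never
  reused across parameter changes; operators replay the stored record
  under the current parameters.
* **Ultrametry.** Tip ages must agree within a $10^{-6}$ relative
  tolerance of the root age on input; larger deviations are an error,
  never silently corrected.

## Fixed-tree inference and parameter recovery

With `fixed_tree = TRUE` the topology/age operators are disabled and the
chain samples parameters and augmentation given the tree — the classical
fixed-phylogeny ClaDS analysis. `parameter_recovery_experiment()` checks
calibration: per replicate, true parameters are drawn from the inference
priors, a tree with 40–60 tips (crown age 25, $\rho = 1$, turnover mode)
is simulated by rejection, and fixed-tree inference is run; the central
90% credible interval for $\sigma_\lambda$ should cover the truth in a
Binomial(n, 0.9) fraction of replicates. Because the truths come from the
same priors the inference uses, and the tip-count/root-age acceptance
window is a function of the data alone, nominal coverage is exact up to
Monte-Carlo error in the interval estimates. The test suite runs a
5-replicate smoke version (a lower tail of 2 or fewer successes has
probability below 0.01 under calibration); the 20-replicate experiment is
one function call.

## Full inference

`run_chain()` co-estimates the tree, the diversification parameters and
the augmentation from a molecular alignment when one is supplied. The
substitution model is deliberately minimal — Jukes–Cantor with a strict
clock, single partition, gaps and `N` treated as fully ambiguous — the
smallest model sufficient to demonstrate joint estimation at desk scale;
GTR-family models, rate heterogeneity across sites, relaxed clocks and
partitions are out of scope. The pruning likelihood is rescaled per node
and checked against brute-force state enumeration on 4-tip trees. The
clock rate is fixed by default; estimating it jointly is supported only
with a free root age, since the two are confounded on a fixed timescale.

## What the synthetic data do and do not show

All validation inputs are simulated from the model itself: the harness
shows the sampler and the densities are mutually consistent, and the
recovery experiment shows the inference is calibrated *when the model is
true*. None of this certifies behaviour on real alignments — model
misspecification (non-lognormal rate shifts, non-uniform sampling,
substitution-model violations) is outside what these tests can detect. An
empirical-scale template configuration (87 taxa, fixed 44 Ma root,
$\rho = 0.98$, turnover mode) ships as
`inst/extdata/cetacean_demo.yaml`; at realistic chain lengths it is a
multi-day run and carries no pass/fail semantics.

## Problem sizes used by the shipped checks

The test suite and the acceptance runs use: harness at 10 taxa, 1,000
logged samples per path (thinning 60); Yule crown-expectation check at
10,000 forward simulations; density/proposal oracle audits on at least
1,000 simulated subtrees; pruning-likelihood audits on 4-tip trees; and
the 5-replicate, 40-60-tip recovery smoke with 60,000-iteration chains.
These sizes are the package's own desk-scale choices; every one of them
is a function argument that can be raised.
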