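---
title: "Methods: taxonomic and functional turnover in peat-bog vegetation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: taxonomic and functional turnover in peat-bog vegetation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`peatturnover` implements an analysis pipeline for the question of whether
taxonomic turnover (which species are where) and functional turnover (which
traits are where) move together along environmental gradients in
*Sphagnum*-dominated peat bogs. This vignette explains each model, the
parameters that matter, the synthetic study system the package ships for
testing, and the numerical and design choices that were genuinely open.

## The indices

For a site with relative abundances $p_i$ the package computes:

* **Gini–Simpson diversity** $D = 1 - \sum_i p_i^2$, the probability that
  two random individuals belong to different taxa. This form (rather than
  inverse Simpson) is required for the redundancy index below to live in
  $[0, 1]$.
* **Rao's quadratic entropy** $Q = \sum_{i,j} p_i p_j d_{ij}$, the expected
  trait dissimilarity between two random individuals, used as functional
  diversity (FD). The taxon dissimilarity $d$ is a Gower matrix over mixed
  traits: quantitative traits contribute $|\Delta|/\mathrm{range}$,
  categorical traits a 0/1 mismatch, combined as an unweighted mean, so
  $d \in [0, 1]$. Zero-range traits carry no information and are dropped
  with a warning. Note that with equal trait weights a duplicated trait
  column does shift the mean when one copy is removed; only a fully
  redundant trait set is invariant to removal.
* **Functional redundancy** $FR = D - Q$: zero when co-occurring species
  are maximally dissimilar (complete divergence), equal to $D$ when traits
  are identical (complete convergence). Because $d \le 1$ implies
  $Q \le D$, $FR \in [0, 1]$.
* **Community-weighted means** $\mathrm{CWM}_j = \sum_i p_i t_{ij}$ per
  quantitative trait; categorical traits return per-level abundance shares.

Between sites the pipeline uses **Bray–Curtis** dissimilarity for taxonomic
turnover and a **Rao decomposition** for functional turnover: for a pair of
sites, the pooled community $(p_x + p_y)/2$ has entropy $Q_\gamma$; with
mean within-site entropy $Q_\alpha$, the default functional beta is the
Jost-corrected excess $(Q_\gamma - Q_\alpha)/(1 - Q_\alpha)$, clipped at
zero. The uncorrected additive excess is available via
`correction = "additive"`. The correction choice is exposed rather than
asserted because the cited decomposition family includes both variants.

All trait-based indices are computed separately per guild (vascular plants
vs bryophytes): the trait sets of the two guilds are disjoint, so a joint
dissimilarity would be meaningless. Taxa identified above species level
(guild `"other"`) pass through taxonomic indices but are excluded from
trait-based ones, since no trait rows exist for grouped taxa.

## Generalized dissimilarity modelling

`fit_gdm()` regresses pairwise compositional dissimilarity on environmental
differences through monotone transforms:
$\hat d_{xy} = 1 - \exp(-\eta)$,
$\eta = \alpha + \sum_k \beta_k\,|I_k(x) - I_k(y)|$, with
$\alpha, \beta \ge 0$. Each predictor enters through three order-2
I-splines (piecewise-quadratic, monotone, 0 at the variable's minimum and
1 at its maximum) with knots at the min/median/max — the de-facto default
for this model family. Geographic great-circle distance enters as one
additional predictor rescaled to $[0, 1]$.

Fitting minimizes the binomial-form deviance of the $[0,1]$ response by
iteratively reweighted least squares with non-negativity enforced at every
step (active-set non-negative least squares on the weighted working
response). Convergence is declared when the deviance changes by less than
`1e-8`, with a 200-iteration cap. Deviance explained is
$100(1 - \mathrm{dev}/\mathrm{dev}_0)$ against the intercept-only model; a
variable's importance is both the drop in deviance explained when it is
refitted out (`variable_importance()`) and the maximum height of its
fitted partial curve (sum of its coefficients).

`backward_eliminate()` implements the selection rule: variables whose
importance is at most 0.5 percentage points are dropped outright; the
remainder are tested by Monte-Carlo permutation of the variable's
*site-level* values (pair differences are rebuilt after permuting, which
respects the dependence among pairs sharing a site), with
$p = (1 + \#\{\Delta_{perm} \ge \Delta_{obs}\})/(n_{perm}+1)$;
non-significant variables are dropped and the procedure iterates to a
fixed point. The default `n_perm = 100` is a desk-scale setting.

The same pair-dependence argument applies to any regression on unfolded
dissimilarities, which is why `decoupling_test()` reports its slope with a
Mantel-style site-permutation p-value rather than the anticonservative
OLS p (1540 pairs carry roughly the information of 56 sites).

## The co-response model

The joint species–environment model is deliberately simpler than a full
latent-variable JSDM: per species, a linear model of `log(1+cover)`
(standardized) on standardized environmental predictors, tied together by
a hierarchical normal prior on each coefficient (mean and variance shared
across species, inverse-gamma hyperpriors, weakly informative constants
$a_0 = 2$, $b_0 = 0.5$, prior mean variance 100). A Gibbs sampler with
conjugate updates runs `n_chains` seeded chains; split-chain potential
scale reduction is reported. Defaults (5 chains, 5000 iterations, 1000
burn-in, thinning 4) are desk-scale; a publication-scale configuration
(5 chains of $10^6$ iterations, 15000 burn-in, thinning 1000, retaining
985 samples per chain) is accepted but not the default.

Species correlations are decomposed into an environmental part
(correlation of the species' environmental linear predictors across the
observed sites, so each variable's realized range weights the similarity)
and a residual part (correlation of residuals). The environmental
correlation is averaged over posterior samples by default: a species whose
response direction is not pinned down by the data then contributes little,
instead of inheriting an arbitrary point-estimate direction that can
exceed any fixed threshold by chance. The point-estimate variant is
available via `method = "point"`.

`build_network()` draws edges where the environmental correlation reaches
0.6 in absolute value (the threshold applies symmetrically to negative
edges; the source analysis leaves the negative case unstated). Clusters
are connected components of the positive-edge graph with at least two
members, labelled by decreasing size; everything else is `"unrelated"`.
Components, not modularity optimization, because the thresholded-network
description is exactly a components construction.

## Re-assembly scenarios and SES

Seven scenarios perturb a guild's community matrix; each is applied
`n_iter` times and scored by the standardized effect size of the site-mean
functional redundancy. `run_scenario()` reports
$\mathrm{SES} = (\overline{FR}_{sim} - FR_{obs})/\mathrm{sd}(FR_{sim})$,
so a scenario that erodes redundancy scores negative; the standalone
`ses()` utility uses the opposite, classic $(obs - sim)/sd$ orientation.

* **NULL1** (occurrence re-assembly): the community matrix is scaled by
  100 to integer "cover units" and randomized by the count quasiswap
  algorithm, preserving all row totals, all column totals and the matrix
  fill exactly while reshuffling which cells are occupied. Fill
  preservation matters: an unconstrained marginal-preserving walk on a
  large-total integer matrix equilibrates to nearly dense tables, which
  inflates richness and evenness and turns the null into an artifact.
* **NULL2** (abundance re-assembly): repeated transfers between the
  diagonal cells of 2×2 submatrices whose four cells are all non-zero,
  with the amount drawn uniformly from the range keeping all four
  positive. This preserves the occurrence mask and both marginal totals
  exactly, on the raw continuous values (no integerization is needed when
  occurrences cannot move). The default walk length is 1000 attempted
  transfers per occupied cell.
* **RANDOM**: each site is rebuilt from `k` uniform draws from the guild
  pool (default: rounded mean observed richness), each species receiving
  one of its own observed non-zero cover values.
* **LOSS1/LOSS2**: all species of co-response cluster I (II) are removed.
  The removal itself is deterministic, so the simulated distribution the
  SES needs is generated by resampling each surviving present species'
  cover from its observed non-zero values each iteration — the same
  abundance-assignment rule RANDOM uses. Sites emptied by the removal are
  flagged and excluded from the FR mean.
* **TURNOVER1/TURNOVER2**: per site, `n_replace = 3` randomly chosen
  present members of the source cluster are replaced by target-cluster
  species not already present, each inheriting one removed species' cover
  (so site totals are conserved when the target pool suffices).
  Replacement operates per site; the alternative matrix-level reading of
  the protocol does not yield a well-defined operation.

## The synthetic study system

`generate_dataset()` builds a 56-site, 63-taxon survey with the structure
the analysis assumes; every stochastic element flows from one seed through
fixed per-stage offsets (environment, traits, abundances), so datasets are
bitwise reproducible and adding species never reshuffles sites.

* **Environment**: sites scattered over a European-like window; mean
  annual temperature falls with latitude, temperature seasonality rises
  with it, precipitation follows an oceanic west–east gradient, and the
  three deposition variables share a longitudinal trend with independent
  noise (so deposition is correlated with, but not redundant to, climate
  — variable selection stays non-trivial). The warm-quarter moisture
  index is computed from generated warm-quarter surrogates.
* **Clusters**: 25 species per cluster respond with slope $\pm$`env_effect`
  (default 1) to the first principal axis of standardized MAT/MAP/−TS;
  9 unrelated and 4 rare species have slope zero. Both guilds alternate
  within every block.
* **Core dominants**: every fifth cluster member is a high-baseline
  dominant, present at nearly every site with large cover, with a trait
  syndrome close to the bog-wide optimum — the *Sphagnum*-carpet /
  dwarf-shrub tier of real bog vegetation. Occasional species have low
  baselines (about a quarter of sites occupied) and wider trait spread.
* **Traits**: quantitative traits load with coefficient 0.8 on one
  stress-tolerance syndrome axis per species (the strong covariation real
  trait databases show); the cluster offset acts on the syndrome, giving
  each trait a standardized between-cluster mean difference of
  0.8 × `trait_shift` (0.4 at the default 0.5), so cluster trait
  distributions overlap strongly.
* **Trait-based assembly**: log-cover includes `0.35 · t_s · h_i`, where
  `h` is a latent microhabitat axis per site (iid standard normal,
  independent of every measured variable — the hummock/lawn mosaic the
  field protocol samples) and `t_s` the species' standardized syndrome
  score. Co-occurring species are thereby functionally more similar than
  random pool draws, which is the mechanism the re-assembly scenarios are
  meant to detect.
* **Abundance model**: lognormal around the expectation (`noise_sd`
  default 0.9) with a hurdle at one cover unit, below which the species
  is absent. Baselines are set so that site richness lands near the
  survey's reported 7 vascular + 5 bryophyte taxa with a 9–32 range;
  abundances are unitless relative cover (the protocol's units are not
  stated, so no unit is pretended). Rare species are thinned to fewer
  than 5 occupied sites to exercise the occupancy filter.

What the generator does *not* emulate: spatial autocorrelation between
nearby sites, zero-inflation beyond the hurdle, trait measurement error,
and taxonomic resolution problems. Passing tests on this system therefore
show that the pipeline recovers structure it is pointed at, not that real
bog data satisfy the same assumptions.

Two empirical notes from working with this system, also reflected in the
test expectations. First, the Rao-decomposition functional beta tracks
abundance turnover mechanically whenever pairwise trait distances are of
comparable magnitude (with constant $d_{ij} = c$ it is exactly $c$ times a
diversity excess), so on a synthetic pool with strong syndrome structure
functional turnover retains a detectable environmental component even
though functional *composition* barely moves; the flat relationships
reported for the field data plausibly ride on much noisier database
traits. Second, a swap-based null's SES compares the observed matrix with
the stationary distribution of the swap kernel, so even a neutral
generator can sit a few SD from the kernel's equilibrium; the fill- and
marginal-preserving NULL1 keeps the dominants pinned and behaves
neutrally here, while NULL2's equilibrium evenness differs somewhat from
lognormal cover draws.

## Problem sizes and numerical choices

Default test and example runs use the 56-site system with desk-scale
settings: 1000 iterations for the NULL scenarios, 200 for the directed
scenarios, `n_perm = 50` and 30-site replicates for the elimination
calibration, and 2 chains × 5000 iterations for cluster recovery. The
IRLS clips fitted dissimilarities to $[10^{-9}, 1-10^{-9}]$ inside the
deviance; `lsqnonneg` handles the constrained step exactly, so
non-negativity never relies on post-hoc clipping of coefficients.
Occupancy uses strict `> 0` on unrounded abundances. CSV output formats
numbers with 17 significant digits so write–read round-trips are bitwise
exact.
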