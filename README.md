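# peatturnover

Tools for asking whether *taxonomic* turnover (which species occur where)
and *functional* turnover (which traits occur where) are coupled along
environmental gradients in *Sphagnum*-dominated peat bogs — and for
testing what non-random species replacement does to the functional
redundancy of these communities. The package is aimed at community
ecologists working with site × species cover matrices, species × trait
tables and site × environment tables; the beta-diversity and null-model
machinery is the same one used in microbiome and metagenome community
analysis.

## What it computes

For a community with relative abundances `p_i` and a Gower trait
dissimilarity `d_ij ∈ [0, 1]`:

* Gini–Simpson diversity `D = 1 − Σ p_i²`, Rao quadratic entropy
  `Q = Σ_ij p_i p_j d_ij` (functional diversity), and functional
  redundancy `FR = D − Q ∈ [0, 1]` (`FR = 0`: complete trait divergence;
  `FR = D`: complete convergence); community-weighted mean traits
  `CWM_j = Σ p_i t_ij`.
* Bray–Curtis taxonomic turnover and a Jost-corrected Rao decomposition
  for functional turnover between site pairs,
  `(Q_γ − Q_α) / (1 − Q_α)` for the pooled vs mean within-site entropy.
* **Generalized dissimilarity modelling** (`fit_gdm`): compositional
  dissimilarity regressed on monotone I-spline transforms of the
  environment, `d̂ = 1 − exp(−η)`, `η = α + Σ β |ΔI(x)|`, `α, β ≥ 0`,
  fitted by iteratively reweighted non-negative least squares on the
  binomial-form deviance, with permutation-based backward elimination
  (`backward_eliminate`) and partial response curves (`partial_curves`).
* **Co-response clustering** (`fit_species_responses`,
  `decompose_correlations`, `build_network`): a hierarchical Gibbs
  sampler over per-species abundance–environment regressions, species
  correlations split into shared-environment vs residual parts, a
  ±0.6-threshold network, and clusters as connected components.
* **Seven re-assembly scenarios** (`run_scenario`): marginal-preserving
  occurrence (NULL1) and abundance (NULL2) randomizations, random
  assembly (RANDOM), cluster removal (LOSS1/LOSS2) and between-cluster
  replacement (TURNOVER1/TURNOVER2), each scored by the standardized
  effect size `SES = (mean FR_sim − FR_obs)/sd(FR_sim)` of site-mean
  functional redundancy (negative = the scenario erodes redundancy).
* Gradient statistics (`stepwise_regression`, `fr_env_models`) and a
  seeded synthetic-data generator (`generate_dataset`) that emulates a
  56-site European bog survey: two species clusters with opposite
  climate responses, ubiquitous trait-central dominants, overlapping
  cluster trait syndromes, and rare species that exercise the
  occupancy filter.

## Worked example

```r
library(peatturnover)

ds <- generate_dataset(synth_config(seed = 1))
ab <- filter_rare_species(ds$abundance)          # drop taxa in < 5 sites
#> filter_rare_species: removed 8 taxa (cl1_sp14:3, cl1_sp24:3, ...)

## taxonomic turnover along the environment
bc  <- bray_curtis(ab)
pt  <- build_pair_table(bc, ds$env, c("MAT", "TS", "MAP", "PS",
                                      "PTwarm", "SOx", "NHx", "NOy"))
fit <- fit_gdm(pt)
fit
#> Generalized dissimilarity model
#>   1540 site pairs, deviance explained 46.29%
#>   variable importance (I-spline max height):
#>     MAT          0.7261
#>     TS           1.3232
#>     MAP          0.7699
#>     PS           0.0773
#>     PTwarm       0.0501
#>     SOx          0.0162
#>     NHx          0.0000
#>     NOy          0.0672
#>     geographic   0.0000

## co-response clusters from the species-environment model
sp  <- fit_species_responses(ab, ds$env, c("MAT", "TS", "MAP"),
                             mcmc_config(n_chains = 2), seed = 1)
net <- build_network(decompose_correlations(sp), threshold = 0.6)
net
#> co-response clusters (threshold 0.6): I=24, II=24, unrelated=7
rand_index(ds$true_cluster[taxa(ab)], net$membership)
#> [1] 0.9589
```

The deviance explained says that about 46% of the null deviance in
pairwise Bray–Curtis dissimilarity is captured by the monotone
environmental transforms, with temperature variables carrying the largest
partial-curve heights; the network recovers the two planted co-response
clusters almost exactly (Rand index 0.96), with most of the slope-free
species left unconnected.

```r
## what would non-random re-assembly do to functional redundancy?
abv <- subset_guild(ab, "vascular")
r <- run_scenario(abv, ds$traits_vascular, ds$true_cluster[taxa(abv)],
                  scenario = "LOSS2", n_iter = 200, seed = 1,
                  guild = "vascular")
r
#> LOSS2 (vascular): FR_obs = 0.4914, SES = -6.12, p = 0.0100 (200 iter)
```

Losing cluster II's species drops the community's functional redundancy
by about six null standard deviations — the community cannot lose a
whole co-response cluster and stay functionally buffered.

(Numbers above are what the calls print for the shown seeds; small
figures vary with the seed.)

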