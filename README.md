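# symbiophy

Comparative phylogenetic analysis of obligate nutritional symbiosis in
insects: how dietary nutrient deficiencies — B vitamins in particular —
relate to the evolutionary gain, maintenance and loss of obligate microbial
symbionts across insect families, and how symbiosis relates to
diversification.

Many insect families feed on diets that lack specific micronutrients and
host intracellular bacteria they cannot live without. Testing the
nutritional hypothesis comparatively takes a chain of methods, all
implemented here:

* **Trait tables** — family-level nutrient profiles built by nested medians
  over food examples, life stages and species, standardized to amount per
  gram; feeding-niche classification; binary codings of symbiosis (>50% of
  species obligate) and vitamin levels (25%/50% quantile cut-offs).
* **Discrete-trait engine** — Mk likelihoods by Felsenstein pruning
  (compiled), MCMC over transition rates, stochastic character maps with
  exact conditional node sampling and uniformization branch histories,
  ancestral-state summaries, origin/loss counts.
* **Correlated evolution** — dependent (8-rate) vs independent (4-rate)
  models of two binary traits on the combined 4-state chain, exponential
  rate priors under a uniform(0,10) hyper-prior, stepping-stone marginal
  likelihoods, and Bayes factors `BF = 2 ΔlnML` with 2/5/10 evidence
  thresholds.
* **Phylogenetic mixed models** — `bpmm()`, a Gibbs/Metropolis sampler for
  single- and multi-response models (Gaussian, binomial-logit,
  Poisson-log) with covariance-structured random effects, unstructured
  across-response covariances, missing-response imputation, phylogenetic
  heritability `ICC = V_phylo / (ΣV + V_e + π²/3)` for logit responses,
  posterior modes/HPD intervals/pMCMC, ancestral node prediction by
  conditional (kriging) draws, and Gelman–Rubin/ESS diagnostics.
* **Transition categories** — classification of ancestral nodes into
  Non→Non, Non→Ob, Ob→Ob, Ob→Non, posterior resampling of classifications,
  and pooled MR-BPMM contrasts of ancestral B5/B9 across categories
  (origin, maintenance, loss).
* **Co-phylogeny** — host×symbiont combination tables, the `h`, `[h]`,
  `[s]`, `[hs]` covariance structures for variance partitioning, and the
  global ParaFit permutation test.
* **Diversification** — Poisson species-richness models with age and
  metabolism, focal-vs-background niche contrasts, sister-pair richness
  models and the log2 richness-ratio analysis.
* **Synthetic data** — generators for ultrametric trees, CTMC traits with
  retained true histories, liability-threshold binary + nutrient traits
  with planted phylogenetic correlation and heritability, richness counts,
  host–symbiont associations with tunable congruence, and food tables —
  each with a ground-truth sidecar.

Trees are `ape::phylo` objects throughout; `phytools`, `ape::parafit` and
`coda` are used only as independent cross-checks in the test suite.

## Worked example

A synthetic end-to-end run on a 150-family tree (about 15 s on one core):

```r
library(symbiophy)
set.seed(5)
cfg <- pipeline_config(seed = 5, sim = sim_config(n_tips = 150, seed = 5))
run <- run_pipeline(cfg, "my_run")
run$scm$origins
#> [1] 7
run$scm$losses
#> [1] 3
round(run$correlation$r_summary, 3)
#>   mode   mean  lower  upper  pMCMC
#> -0.577 -0.532 -0.775 -0.266  0.002
run$cophylogeny$p_value
#> [1] 0.002
run$diversification$n_pairs
#> [1] 50
```

The stochastic-character-map stage reconstructs 7 origins and 3 losses of
obligate symbiosis on this simulated history; the mixed-model stage
recovers the planted negative phylogenetic correlation (−0.4) between the
symbiosis liability and the first nutrient with a credible interval well
away from zero; the ParaFit stage flags the perfectly congruent
host–symbiont association (p = 0.002); and 50 sister pairs are extracted
for the richness contrasts. `my_run/` holds the family table, ancestral
states, sister pairs, a truth sidecar and a manifest with content hashes;
re-running with the same seed reproduces the hashes bit-for-bit.

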