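---
title: "Comparative phylogenetic methods for obligate nutritional symbiosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative phylogenetic methods for obligate nutritional symbiosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Many insect lineages depend on intracellular bacterial symbionts that they
cannot live without. A leading explanation is nutritional: diets that are
chronically poor in specific micronutrients — B vitamins above all — favour
the evolution and retention of symbionts that synthesize them. Testing this
idea comparatively requires a chain of machinery: a family-level trait table
built from food-composition records; discrete-trait models of how obligate
symbiosis is gained and lost on a time-calibrated phylogeny; tests of
correlated evolution between symbiosis and vitamin levels; phylogenetic
mixed models linking the proportion of symbiotic species per family to
continuous nutrient traits; host–symbiont co-phylogenetic variance
partitioning; and sister-clade comparisons of species richness.

`symbiophy` implements that chain end to end and ships a synthetic-data
generator with known ground truth, so every stage can be calibrated and
stress-tested without any external downloads. Reproducing the published
empirical numbers requires the original data deposit and reference
phylogeny, which are not bundled; all tests and the acceptance script run
on synthetic data whose generating parameters are known exactly.

# Trait-table construction

Nutrient values flow through five aggregation steps: per-nutrient medians
across example foods within a food type; division by the mean item weight
(amount per gram, making wet- and dry-weight sources comparable);
per-life-stage medians across a species' foods — omnivores instead average
across all foods, applied within each stage; the species value as the median
of adult and juvenile; and the family value as the median across species.
Medians of even-sized samples are the mean of the two middle order
statistics. Nutrients missing in more than 30% of families are dropped
(strict `>`); continuous traits are z-transformed (sample sd) before
modelling; missingness is preserved, never imputed at table time —
model-based imputation happens inside the mixed model.

Binary codings: a family is "obligate" when strictly more than half of its
resolved species carry obligate symbionts (species with unresolved status
are excluded from numerator and denominator). Vitamin levels are coded
low/high at both the 25% and 50% across-family quantiles, computed with
type-7 (linear interpolation) quantiles; values exactly at a threshold are
"low". Both conventions are configurable because the discretization depends
on them.

Family feeding niches: any omnivorous/detritivorous member species makes the
family omnivorous; specialist niches (phloem, xylem, wood, blood, predator,
fungivore) require more than half of classified species to feed exclusively
there (the "most species, if not all" rule, with the fraction configurable);
remaining plant-feeders are generalist herbivores.

# Trees

Trees are handled as `ape::phylo` objects. Families with trait data but
absent from the reference phylogeny are grafted onto the stem branch of
their published sister taxon. The attachment depth along the stem is not
determined by the published description, so both options are implemented:
midpoint (default) and just below the parent node (`stem_top`, offset by
1e-8 Myr to avoid zero-length branches); neither is asserted to be the
original choice. Grafted tips are flagged and excluded from age-sensitive
analyses by default. The phylogenetic covariance `C[i, j]` is the
root-to-MRCA depth; internal nodes can be included (with auto-generated
`N<number>` labels) for node-level models.

# Discrete-trait engine

The Mk likelihood uses Felsenstein pruning with per-branch matrix
exponentials, computed by eigendecomposition with a scaling-and-squaring
fallback for near-defective generators (compiled in C++). The root state is
integrated over a uniform prior by default (stationary available). Rate
posteriors come from a random-walk Metropolis sampler on log rates with an
exponential prior whose mean defaults to the parsimony change count divided
by total tree length; proposals adapt during burn-in towards 20–40%
acceptance.

Stochastic character maps first draw joint ancestral node states from their
exact conditional distribution (root from the rescaled root partials, then
children given parents in preorder), then fill in within-branch histories
conditioned on the endpoints by uniformization, which is exact. Ancestral
summaries follow two rules: for the binary symbiosis trait, a node is
assigned its modal state only when its map frequency strictly exceeds 0.5,
otherwise it is "uncertain" and its edges are excluded from origin/loss
counts (conservative with respect to the ancestral, non-symbiotic state);
for multi-state niches the plurality state is assigned with no 0.5
requirement. Origins and losses are counted at the node level — within-branch
multiple hits exist in the maps but do not enter the headline counts.

A note on calibration testing: map-based node frequencies are compared with
the exact marginals from two-pass pruning. The `3 x sqrt(p(1-p)/n)`
Monte-Carlo band is a normal approximation that breaks down when a marginal
sits within a count or two of 0 or 1, so the test suite applies it only for
marginals in `[0.01, 0.99]` and uses an exact binomial tail test (at the
equivalent significance level) at the extremes.

# Correlated evolution of two binary traits

The paired-trait model runs the pruning engine on the combined four-state
chain `00, 01, 10, 11` with dual transitions fixed at zero: four free rates
under independence, eight under dependence; constraining the dependent rates
pairwise reproduces the independent likelihood exactly. Rates get
exponential priors whose mean is itself uniform on (0, 10). That published
hyper-prior is stated as seeding "the mean and variance" of the exponential;
a one-parameter exponential cannot take both, so the mean alone is seeded —
a documented reading of an ambiguous description.

Marginal likelihoods use stepping-stone sampling along power posteriors with
temperatures at quantiles of Beta(0.3, 1), warm-starting each stone. Support
is summarized as `BF = 2 (lnML_dependent − lnML_independent)` with the
2/5/10 thresholds for positive/strong/very strong evidence. The stepping
stone routine is generic (any log-likelihood/log-prior pair over an
unconstrained parameter vector), which is how it is validated against the
Beta–Bernoulli closed form.

A known limitation: the shared hyper-prior shrinks extreme rates strongly,
so posterior ratios between a very fast and a very slow rate understate the
true asymmetry; a 30-fold planted asymmetry is reliably detected as strong
and right-signed, but its point estimate is not recovered within a factor
of two at these data sizes. Tests assert the former, not the latter.

# The phylogenetic mixed model

`bpmm()` is a Gibbs/Metropolis sampler for single- and multi-response
models with Gaussian, binomial(logit) and Poisson(log) responses. Every
response cell carries a latent liability: observed Gaussian cells are their
own liability; missing Gaussian cells are imputed by data augmentation;
binomial and Poisson cells get adaptive random-walk Metropolis updates of
their liabilities against a conditional-normal prior. Each response
receives its own coefficient for every design column (trait-specific
intercepts; no global intercept).

Random terms are matrix-normal: levels follow the supplied covariance
(phylogenetic or identity), responses follow a per-term covariance `G`,
either diagonal ("shared") or unstructured. When the data balance the term
(equal rows per level — one row per tip being the common case), effects are
updated in the eigenbasis of the covariance, which block-diagonalizes the
full conditional into per-level p-dimensional draws and keeps each sweep
O(n); unbalanced terms (e.g. host-identity effects over combination rows)
fall back to a dense multivariate draw, acceptable at their small sizes.
Variance matrices get conjugate inverse-Wishart updates with the (V, nu)
parameterization, defaults `V = diag(p)`, `nu = p − 1 + 0.002`. The
parameter-expanded prior variant is not implemented: it is a mixing aid for
samplers whose variance updates mix poorly, and the rotated conjugate
updates here do not need it.

The binomial residual variance is not identifiable and is fixed at 1 on the
latent scale whenever the residual structure is diagonal (the default for
models with non-Gaussian responses); the binomial fixed-effect prior
variance defaults to that fixed residual plus `pi^2/3`, approximately flat
on the probability scale. Variance partitioning reports
`ICC = V_term / (sum V_terms + V_e + link variance)` with link variance
`pi^2/3` for logit responses and 0 otherwise; between-response correlations
come from the unstructured `G` (and residual, where unstructured) draws.
Summaries report KDE posterior modes (Silverman bandwidth), 95% highest-
density intervals (quantile intervals were the alternative; HPD matches how
posterior modes are reported), and
`pMCMC = 2 min(#{x<=0}+1, #{x>=0}+1)/(N+1)` capped at 1.

Ancestral predictions draw internal-node random effects from their
conditional multivariate normal given the tip effects (kriging against the
tips+nodes covariance), one draw per retained iteration, add the node-level
fixed predictor and apply the inverse link; a plug-in conditional-mean mode
exists for quick checks. Convergence diagnostics (PSRF against a 1.1
threshold, initial-positive-sequence ESS, autocorrelation) are implemented
in the package and cross-checked against `coda` in the tests.

# Transition categories and ancestral B vitamins

Internal nodes are classified by their own obligate state and their
immediate descendants: Non→Non, Non→Ob (at least one obligate descendant),
Ob→Ob, Ob→Non (at least one non-obligate descendant). Classification
uncertainty is propagated by resampling: each of (by default) 100 resamples
takes one posterior draw of the node probabilities from the binomial BPMM,
thresholds at 0.5, reclassifies, and refits a Gaussian MR-BPMM of
node-level B5/B9 values on the four-level category factor with the
phylogenetic covariance linked to node labels; a few draws are retained per
resample and pooled (the 100 x 10 = 1,000-draw shape at full scale; the
desk-scale defaults keep 10 draws per resample at roughly 1/100 the cost).
Contrasts follow the later-minus-earlier convention: origin = Non→Ob −
Non→Non, maintenance = Ob→Ob − Non→Non, loss = Ob→Non − Ob→Ob.

The node-level nutrient values are an input to this module. In the two-step
wiring they are the ancestral expectations from a BPMM of tip nutrients
(`predict_nodes` on the continuous traits); the calibration tests instead
supply true node values plus noise, because kriged node estimates borrow
strength from descendants and therefore leak a little of the post-origin
decline into the pre-origin nodes — a property of any two-step
reconstruction, not of the category machinery being tested. Both wirings
are supported.

# Co-phylogeny

The combination table crosses host families with symbiont lineages and
counts species sampled with and without each symbiont; vertically
transmitted lineages can be excluded. Four covariance structures over the
rows quantify where variation in obligate symbiosis sits: `h` (host
identity), `[h]` (host phylogeny, expanded), `[s]` (symbiont phylogeny,
expanded), `[hs]` (elementwise product, PSD by the Schur product theorem);
phylogenetic covariances are scaled to unit diagonal before expansion. The
published analysis fits `h`, `[h]`, `[hs]` for symbiosis and all four for
the B-vitamin models; the caller chooses the subset.

The global ParaFit statistic is the sum of squared elements of the
fourth-corner matrix of principal coordinates of the two patristic distance
matrices (Lingoes correction when negative eigenvalues appear); the
permutation null shuffles each symbiont's host links, `p = (1 + #{perm >=
obs}) / (n_perm + 1)`, 1000 permutations by default. The statistic is
verified equal to the `ape` implementation in the tests; only the global
test is exposed, since link-level tests are not part of the reported
analysis.

# Diversification

Species richness is modelled directly (Poisson, log link) rather than as a
derived diversification rate. The main model is an MR-BPMM of richness and
the binomial symbiosis proportion with z-transformed family age and
holo/hemimetaboly as fixed effects; the quantity of interest is the
phylogenetic correlation between the two responses. Focal-cell contrasts
refit richness with a two-level focal-versus-background factor per
niche-by-symbiosis cell. Sister analyses use the cherries of the tree:
a Poisson model of richness on the empirically logit-transformed percentage
of obligate species (`log((k+0.5)/(n-k+0.5))`, finite at 0% and 100%), pair
age and niche, with pair identity and pair nodes (linked to the phylogeny)
as random effects; and a Gaussian model of `log2` richness ratios for pairs
that differ in symbiosis, oriented so the higher-percentage family is the
numerator — the estimate is invariant to reorientation by antisymmetry.
Grafted families are excluded by default.

# The synthetic-data generator

The generator defines the study conditions for all calibration tests:

* **Trees**: birth–death conditioned on the tip count (`ape::rphylo`),
  rescaled to a 400-Myr root age to echo the insect family timescale;
  150 tips by default — enough signal for recovery tests, small enough for
  minutes-long fits.
* **Binary trait**: either a CTMC simulated root-to-tips with full history
  retained (the oracle for the discrete engine), or the liability-threshold
  route below (the oracle for the mixed model). Two generators, deliberately,
  because each matches the assumptions of the machinery it tests.
* **Liabilities and nutrients**: multivariate Brownian motion on the tree
  with a specified cross-trait correlation matrix; per-trait phylogenetic
  heritability (default 0.8, inside the 0.71–0.96 range reported for real
  nutrient traits) imposed by mixing in independent noise. The first
  liability maps through the inverse logit to a per-family probability, and
  family counts are binomial in the number of species sampled (default 10)
  — exactly the generative structure the binomial-logit BPMM assumes.
  Default planted correlation −0.4; nutrient missingness 5%.
* **Richness**: Poisson with log-rate `base + age effect + trait effect +
  Brownian clade effect`, truncated at 1.
* **Host–symbiont associations**: the symbiont tree mirrors the host tree
  (branch lengths jittered 10%); each symbiont keeps its co-diverging host
  with probability `signal`, else switches uniformly.
* **Food tables**: food types with lognormal within-type noise around known
  per-gram levels, plus species diets and family metadata.

Every generator returns a truth object sufficient to score recovery without
re-reading code, serializable as JSON. What the generator does not emulate:
the real taxon sampling, the empirical nutrient marginals, diet
non-independence across related families, or rate shifts in nutrient
evolution — so passing tests demonstrate correctness and calibration of the
machinery under its own assumptions, not robustness to every feature of the
real data.

# Problem sizes and numerical choices

The test suite and acceptance script run everything at desk scale, chosen
so the whole suite completes in well under half an hour on one core:
enumeration checks on trees of 3–5 tips (100 cases); stochastic-map
calibration on 50-tip trees with 1,000 maps; stepping stones at the
published 100 x 1,000 setting for the closed-form toy and 25 x 250 for the
Bayes-factor discrimination runs (20 + 20 datasets of 150 tips in the test
suite, 10 + 10 in the acceptance script); 100 bivariate mixed-model fits of
150 tips (40 in the acceptance script) with 2,500-iteration chains;
transition-category replicates on 100-tip trees with 10 posterior
resamples; ParaFit nulls with 99 permutations per simulation. Paper-scale
chain settings (millions of iterations, 100 resamples, 1,000 permutations)
remain available through the ordinary arguments.

Numerical conventions: eigenvalues of covariance matrices are floored at
1e-10; graft-induced zero-length branches are perturbed by 1e-8 Myr;
transition-probability rows are clipped at 0 and renormalized against
round-off; the uniformization path sampler caps virtual jumps at 10,000;
MH step sizes adapt only during burn-in, keeping the retained chain a valid
fixed-kernel sample. Ties at discretization thresholds go to "low"; ties at
the 0.5 ancestral-state rule go to "uncertain" (binary) or the plurality
state (multi-state).

# Known limitations

* Node-probability thresholding at 0.5 discards calibration information;
  the resampling scheme restores it only to the extent the posterior is
  well mixed.
* Rate-ratio point estimates under the shared exponential hyper-prior are
  shrunk towards unity (see above); use Bayes factors, not ratio
  magnitudes, for claims about state dependence.
* The Poisson richness model has no zero-inflation or negative-binomial
  option; clade overdispersion is absorbed by the additive latent residual.
* No reversible-jump exploration of rate-equality partitions, no
  event-based co-phylogenetic reconciliation, and no tree inference — trees
  are inputs.
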