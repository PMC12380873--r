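---
title: "Methods: germplasm performance evaluation and introduction adaptability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: germplasm performance evaluation and introduction adaptability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

forageadapt implements a two-sided workflow common in forage agronomy:
field-side comprehensive evaluation of germplasm performance from replicated
agronomic trait measurements, and map-side prediction of where the selected
germplasms can be introduced, using an ensemble species distribution model
(SDM) and environmental similarity.  This vignette documents the models, the
parameters that matter, the synthetic-data generator that makes the whole
pipeline testable offline, and the design decisions taken where the methods
literature leaves genuine freedom.

## 1. The trait side

### Descriptive and variation statistics

`trait_describe()` reports min, max, mean, the sample (n−1) standard
deviation and the coefficient of variation CV = 100·std/mean.  Variation
tables in agronomy are sometimes computed with the population (1/n) sd; we
use the sample sd, the SPSS default, and document it here because published
tables rarely say.  `describe_traits()` computes these statistics over
*germplasm means* (one value per germplasm, averaged over replicates), not
over raw replicates — the usual semantics of a trait-level variation table.

### Leaf area

Oat leaf area is approximated from blade length and width with a shape
correction, `area = length × width × R`, with R = 0.8317 by default
(`leaf_area()`).  R is dimensionless; lengths are cm, areas cm².

### Shannon trait diversity

`shannon_trait_diversity()` treats each trait's replicate vector as a
share distribution: H_t = −Σ p_i log p_i with p_i the replicate's share of
the trait total, and reports the **sum over traits**.  A single Shannon
index over a 23-trait vector is bounded by log 23 ≈ 3.14; published
per-germplasm diversity values for this kind of design lie in the 10–22
range, which is only reachable as a sum of per-trait indices bounded by
n_traits·log(n_reps) = 23·log 10 ≈ 52.98.  The summed definition is
therefore the one compatible with practice; it is a documented choice, and
the per-trait components are exposed so any other aggregation can be built.

### Correlations

`pearson_matrix()` reports Pearson r with two-tailed p-values from the
t transform with n−2 degrees of freedom.  Correlations, grey relational
analysis, PCA and membership scoring all operate on germplasm trait
*means*; replicate-level data enter only the descriptive statistics and
Shannon diversity.

### Entropy weights

`entropy_weights()` implements the classic entropy weight method on a
min-max normalized matrix: column shares p_ij = x_ij/Σ_i x_ij, normalized
entropy e_j = −(1/log n)Σ p log p, divergence d_j = 1 − e_j, weights
w_j = d_j/Σ d_j.  Constant (and all-zero) columns carry no information and
get weight 0; an all-constant matrix falls back to uniform weights with a
warning rather than dividing by zero.

### Grey relational analysis

`grey_relational()` implements Deng's relational degree with resolution
coefficient ρ (default 0.5).  Two conventions are deliberately fixed:

* Δmin and Δmax are **global** over all factors and observations (the
  two-level min/max), the standard Deng convention; method descriptions
  often omit this.
* The relational degree aggregates per-observation coefficients ξ_i(k) by
  **observation weights**, uniform by default.  When the factors are traits
  and the observations germplasms, entropy weights computed over germplasms
  can be supplied through `obs_weights`, reproducing the
  "entropy-weighted, then grey correlation" workflow.  Both weighted and
  plain Deng aggregation are available because published tables rarely say
  which was used.

γ is scale-invariant once inputs are min-max normalized (a property the
tests check), so the normalization step is a precondition, not decoration.

### Ridge path analysis

Forage yield constituents are strongly collinear, so path analysis uses a
ridge-regularized solve.  With population-sd standardized data the solution
is β(k) = (R_xx + kI)⁻¹ r_xy; the indirect effect of trait i via trait j is
r_ij·β_j, and at k = 0 direct + indirect reproduces r_iy exactly — the
classical path-decomposition identity, enforced in tests to 1e−9.  Choices:

* **Standardization** uses the population (1/n) sd so that X'X/n is exactly
  the correlation matrix.  Commercial implementations do not document their
  convention; ours is stated and tested.
* **k selection**: no selection rule is standard in the agronomy use of
  ridge path analysis, so `k = "auto"` minimizes leave-one-out
  cross-validated squared error on a log grid in [1e−4, 1], and any fixed
  k ≥ 0 can be forced.
* The fresh-yield model excludes the hay-side variables (HY, HFR, HYS,
  HYL); the hay-yield model may include fresh yield and the hay components.
  Both predictor sets are configurable in the pipeline.

### PCA contributions and trait selection

`pca_contributions()` runs PCA on the correlation scale, retains axes until
the cumulative explained variance reaches `var_target` (default 60 %), and
defines a trait's contribution as the eigenvalue-weighted mean of its
squared loadings over retained axes, scaled to sum to 100.  The selection
threshold "contribution ≥ 1" seen in applied papers is ambiguous (percent of
what?); our default flags traits at or above the **uniform share** 100/m,
and a literal percent threshold can be passed instead.

### Membership scoring and cluster cuts

`membership_scores()` is the fuzzy membership-function evaluation: each
selected trait maps to [0, 1] by min-max position, reversed for cost
traits, and the germplasm score is the weighted mean (equal weights by
default; entropy weights can be supplied — published workflows are split,
and ours is stated).  Default orientations mark thousand kernel weight
(TKW) and seed width (SW) as cost traits, following their negative
correlation with forage yield; all others are benefit traits.

`hcluster_cut()` cuts an agglomerative dendrogram at a fixed Euclidean
height.  Linkage is configurable (`average` default; 1-D yield clusterings
at the usual cut heights are insensitive to it) and classes are labelled
A, B, ... by descending class mean so "A" is always the top class.

## 2. The map side

### Occurrence handling

`clean_occurrences()` applies the standard desk rules: non-finite and
out-of-range coordinates, exact (0, 0) points, exact duplicates, and points
outside the study extent, with per-rule counts reported.  This is a
deliberate reduction of full coordinate-cleaning taxonomies to the rules
that matter for synthetic and pre-filtered data.  `rarefy_occurrences()`
thins to one point per grid cell (e.g. 5 arc-minutes) with a seeded uniform
choice of survivor.

### Collinearity filter

`collinearity_filter()` iteratively removes layers until all pairwise
|Pearson r| < 0.80 (configurable), dropping from the worst pair the layer
with the larger mean absolute correlation to everything else — a greedy
rule that keeps the more independent member.

### Ensemble model

`fit_ensemble()` follows the ensemble-SDM recipe: balanced pseudo-absences
sampled uniformly outside presence cells; repeated stratified 75/25
holdouts (default 10 repeats; the demo pipeline uses 3 for speed); one AUC
per learner per repeat; learners whose mean holdout AUC reaches 0.75 enter
the consensus with weights proportional to AUC; the consensus raster is the
weighted mean probability.  TSS, Kappa and AUC of the ensemble are computed
on pooled holdout predictions, binarized at the TSS-maximizing threshold
(no binarization rule is standard; max-TSS is the common SDM choice).

The nine named algorithms of the reference ensemble tooling (MAXENT, GLM,
GAM, MARS, GBM, CTA, RF, ANN, SVM) are represented here by five learner
*families* buildable from the available numerical stack: ridge-regularized
linear logistic and degree-2 polynomial logistic (glmnet), spline logistic
(mgcv), k-nearest-neighbour probability and AdaBoost decision stumps (both
implemented in the package).  The fidelity target is the ensemble
*mechanism* — AUC gating, AUC weighting, consensus averaging — not the
exact algorithm roster.

`variable_importance()` permutes one covariate at a time (seeded), and
scores 1 − r between intact and permuted consensus predictions, floored at
zero and normalized to 100.

### Suitability classification and geography

`jenks_breaks()` is an exact Fisher-Jenks dynamic program (compiled via
Rcpp) minimizing within-class sum of squared deviations; tests verify it
against exhaustive partition search for n ≤ 12.  `classify_suitability()`
uses half-open intervals with the boundary value going to the **lower**
class — reclassification tools differ here and rarely document it, so the
convention is fixed and tested.  Cell areas use the authalic sphere
(R = 6371.0088 km): A = R²·Δλ·|sin φ₂ − sin φ₁|, which partitions the
sphere exactly.  Regional summaries assign each cell to the region
containing its center (first match on overlap, with a warning) rather than
clipping polygons: simpler, and the quantization error vanishes with
resolution.  Class centroids are area-weighted means of cell centers in
lon/lat — adequate at regional scale — and centroid migration uses the
haversine distance with an eight-sector compass label.

Period-to-period change is computed from areas (100·(A₂−A₁)/A₁ per class);
where a class starts from zero area the percent change is reported missing
rather than infinite.

## 3. Introduction adaptability

`region_profiles()` extracts per-region mean/median suitability, mean
environmental features and suitable area.  `optimal_dissimilarity()`
screens candidate indices (Euclidean, Manhattan, Bray-Curtis, Gower) by the
Spearman correlation between pairwise profile dissimilarities and pairwise
suitability differences, choosing the best-aligned index (ties go to the
first candidate; indices undefined on the features, e.g. Bray-Curtis on
signed values, are screened out).  `mantel_test()` permutes rows and
columns of one matrix jointly; for n ≤ 6 it enumerates all permutations and
the p-value is exact, otherwise p = (1 + #{perm ≥ obs})/(perms + 1).

The germplasm-by-region adaptability score is a documented reconstruction,
since the combination of entropy-weighted trait performance with regional
suitability is not operationally specified anywhere we could follow:

A(g, r) = M(g) · S̄(r) · (1 + sim(r)) / 2

with M(g) the membership comprehensive score, S̄(r) the region's mean
suitability and sim(r) the Spearman correlation between the region's
environmental profile and the trial site's.  The score is in [0, 1],
monotone in each ingredient, zero wherever the region is unsuitable, and
maximal exactly when a perfect germplasm meets a fully suitable region that
mirrors the trial site.  Significance per region is a permutation p-value
of sim(r) under random reordering of the trial-site features; scores are
classified none/low/high by Fisher-Jenks over all pairs; and the
region-by-region Spearman matrix is exposed separately so distance-matrix
readings (region×region, germplasm×germplasm, or bipartite) can all be
assembled from the same building blocks.

## 4. The synthetic world

`generate_trait_table()` draws a latent yield potential per germplasm,
latent ~ N(0, germplasm_sd), and builds each trait's replicates as
baseline_t + sign_t·latent·scale_t + N(0, replicate_sd·scale_t).  Defaults
follow the field design this package targets: 62 germplasms, 23 traits with
field-realistic baselines, 10 replicates, 19/62 germplasms flagged as not
completing the fertility period (a flag, not missing rows, so filtering is
an explicit, testable step).  Replicate noise is scaled per trait so that
germplasm_sd/replicate_sd is the signal-to-noise ratio *uniformly across
traits*; with a constant absolute noise term instead, the recovery
properties quoted in terms of that ratio would silently depend on each
trait's measurement scale.  Thousand kernel weight and seed width carry
sign −1; hay/fresh ratio, seed length, leaf layers and fertile tiller count
are yield-neutral (sign 0), so the generated world contains genuinely
uninformative traits for the selection steps to reject.

`generate_landscape()` builds each environmental layer as a sum of seeded
low-frequency sinusoids plus lightly smoothed white noise — cheap, smooth
and bit-reproducible across platforms, unlike Gaussian-process simulation —
standardized per layer.  The true suitability is logistic in two named
layers (defaults 2.5 and −1.8 with intercept −0.5, giving a grid-mean
suitability near 0.45 and strong spatial structure).  Occurrences are
sampled presence-only, with probability proportional to true suitability
(no true absences, mirroring pseudo-absence workflows).  Regions are a
rectangular tiling of the extent with ids SP01, SP02, ...

What a green test on this world establishes: that the estimators recover
constructions they should recover (signs, rankings, logistic truth,
engineered similarity) at the stated noise levels.  What it does not
establish: behaviour under sampling bias, spatially structured detection
error, non-logistic truth, correlated replicate errors, or real climate
collinearity structure — none of which the generator emulates.

## 5. Numerical choices and degenerate inputs

* Min-max normalization of a constant column yields 0 with a warning (its
  entropy weight is then 0); normalization is idempotent on normalized
  non-constant input.
* Grey relational analysis with all factors identical to the reference
  returns all degrees 1 with a warning (Δmax = 0).
* `jenks_breaks()` requires at least k distinct values; `cut_height ≤ 0`
  in `hcluster_cut()` yields singletons by definition rather than relying
  on dendrogram tie behaviour.
* Mantel p-values are never 0: exact mode includes the identity
  permutation, sampling mode uses the +1 correction.
* The CV of a zero-mean vector, and the percent change of a class with
  zero initial area, are reported missing with a warning, not as Inf.
* All stochastic steps take explicit seeds; the pipeline derives per-stage
  seeds from one master seed, and two runs with the same configuration are
  byte-identical (tested).

## 6. Configuration formats

Pipeline configs are JSON (read with jsonlite); YAML is accepted by
`read_config()` when the yaml package happens to be installed, but nothing
in the package depends on it.  Rasters are ESRI ASCII grids written with
17 significant digits so write/read round trips are bit-exact; regions are
GeoJSON FeatureCollections; trait tables are long-format CSV.

## 7. Known limitations

* The SDM learners are desk-scale stand-ins; no MaxEnt feature classes, no
  neural networks, no tree ensembles beyond boosted stumps.
* Areas and centroids use cell-center assignment and lon/lat weighting, not
  equal-area reprojection; errors are second-order at regional scale but
  real at continental scale.
* The adaptability score A(g, r) is this package's own construction
  (Section 3); its absolute values are not comparable across studies,
  though its ordering properties are tested.
* Published headline metrics that depend on proprietary occurrence and
  climate data (ensemble AUC/Kappa/TSS on real data, real per-region
  areas) are outside what a synthetic world can reproduce and are treated
  as non-targets throughout.
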