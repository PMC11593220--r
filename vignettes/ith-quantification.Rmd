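---
title: "Quantifying intra-tumor heterogeneity from digital pathology label maps"
author: "ithquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intra-tumor heterogeneity from digital pathology label maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ithquant)
```

# The problem

Breast tumors are spatially heterogeneous: regions of one tumor can differ
in differentiation (grade), stromal composition, and immune infiltration.
This morphologic intra-tumor heterogeneity (ITH) carries prognostic
information, but it is hard to assess visually and reproducibly.
`ithquant` quantifies spatial ITH from the *label maps* that modern
segmentation models produce for a whole-slide image (WSI): a region map
(tumor / tumor-associated stroma / other), a classified nuclei point set,
and patch-level digital grade and pleomorphism predictions, with an
in-situ (DCIS) mask that must be excluded from all analysis. The package
does not train or run any segmentation network; its inputs are label maps,
and a synthetic generator stands in for them during validation.

# From label maps to a patch grid

All features are computed on a grid of non-overlapping square patches of
side 62 µm tiling the maps from the top-left. We read the patch size
"62 µm" as a *side* length (area 3844 µm²): a patch of 62 µm² area would
have a side of roughly 8 µm — smaller than a single tumor cell — and could
not carry the multi-cell texture the features describe. The side is
configurable (`patch_side_um`).

For every patch `k` and binary layer `l`, `patchify()` records the
labelled-pixel fraction `f(k, l)`. A patch is *valid* when its tissue
coverage is at least 50% and it has **no** DCIS overlap; invalid patches
never enter any feature sum. The tissue threshold and the strict DCIS rule
are package choices: exclusion itself is mandated by the analysis design,
but no numeric threshold accompanies it, and erring toward purity costs
only a few patches. Graded layer groups (grade, pleomorphism) are also
summarized as a dominant level per patch (argmax of the level fractions,
ties broken toward the lower level, so a tie can never inflate apparent
grade).

Nuclei arrive as full-resolution centroids and are rasterized onto the
five-times down-sampled frame (`rasterizeCells()`): each nucleus sets the
pixel at `(floor(x/5), floor(y/5))` to its class code. When several nuclei
collide on one pixel, points are processed in `(y, x, class code)` order
and the last write wins — an arbitrary but documented rule that makes the
raster bit-exact reproducible.

# Texture features

For each analysis layer we form a presence/absence patch map by
thresholding its fraction: threshold 0.1 for dense layers (regions, grade,
pleomorphism, differentiation components) and 0.01 for the five nuclei
layers, whose rasterized centroids occupy only a few percent of a patch's
pixels (a 0.1 threshold would declare them absent everywhere). Both
thresholds live in the catalogue and can be changed per layer.

`buildCoocMatrix()` counts, over the eight unit-offset directions, how
often level `i` neighbours level `j` among valid patches; the count is
divided by two (each unordered pair once) and normalized to sum one,
giving the symmetric co-occurrence matrix `p(i, j)`. From it
`textureStats()` computes, with `i, j` the level values:

* contrast `Σ p(i,j) (i−j)²` — 0 exactly for a constant map;
* dissimilarity `Σ p(i,j) |i−j|` — the linear off-diagonal statistic;
* homogeneity `Σ p(i,j) / (1 + (i−j)²)` ∈ [0, 1];
* **heterogeneity = 1 − homogeneity**, the statistic the ITH score is
  named for;
* correlation `Σ p(i,j)(i−μᵢ)(j−μⱼ)/(σᵢσⱼ)`, defined as 0 and flagged
  when a marginal variance vanishes;
* uniformity `Σ p(i,j)²` ∈ [0, 1] and energy `sqrt(uniformity)`;
* entropy `−Σ p log₂ p ≥ 0`.

Uniformity ("sum of squared elements") and energy are sometimes described
interchangeably with contrast-like wording; we emit both readings —
uniformity/energy as above and dissimilarity as the linear-off-diagonal
statistic — so either convention is available.

`colocalization(a, b) = Σ min(aₖ,bₖ) / Σ max(aₖ,bₖ)` compares two fraction
layers across patches: 0 iff their supports are disjoint, 1 iff the same
fraction of both is found together in every patch.

Degenerate statistics — a co-occurrence matrix with no valid neighbour
pair, a correlation on a constant map, a colocalization of two empty
layers — are recorded as missing (`NA`), never silently propagated:
missingness is data and is excluded pairwise downstream.

# The 162-feature catalogue

The default catalogue (`defaultCatalogue()`) has 18 layers × 8 texture
statistics = 144 features plus 18 designated colocalization pairs = 162
features per patient. The layers: three region layers, five nuclei layers
(tumor, intratumoral immune, stromal immune, connective,
normal-epithelial), three digital-grade and three pleomorphism levels, and
four differentiation components (tubule-forming, mitosis-rich,
high-cellularity, discohesive-architecture). Every feature belongs to one
family: grade / pleomorphism / differentiation-component / tumor-nuclei /
normal-epithelial-nuclei features to **differentiation**, region and
connective features to **stroma**, immune features to **TILs**. The
assignment of the non-immune nuclei classes is a package choice (tumor and
normal-epithelial nuclei describe the epithelial compartment's
differentiation; connective nuclei describe stroma). The catalogue is an
ordinary data structure — YAML-serializable, fully configurable — and the
`162` total is a reconstruction: the catalogue's exact composition is a
documented default, not a canonical list.

# Scores

`scaleFeatures()` min-max normalizes each feature to [0, 100] across the
cohort; constant features carry no cohort information and are dropped with
a warning. `familyScore()` averages the scaled member features of one
family per patient (pairwise-complete), giving three family heterogeneity
scores in [0, 100].

The overall ITH score is assembled in two steps. `screenFeatures()` fits a
univariate Cox model per feature and retains those with Wald p < α
(default 0.05). `fitITHModel()` then fits one multivariate Cox model on
the retained features and defines

`score = a + Σ bᵢ xᵢ`

with the multivariate coefficients `bᵢ`. The Cox partial likelihood has no
intercept, so `a = 0` by default (it is kept as a configurable offset
because the score formula is conventionally written with one). Three
pragmatic guards make the fit total on high-dimensional screens: features
with pairwise |r| > 0.95 are pruned (keeping the lower univariate p);
when events fall below 10 per retained covariate, or the unpenalized fit
fails, a small ridge penalty (default 0.01) is applied with a warning; and
missing feature values are imputed with the per-feature cohort median —
pairwise deletion is impossible in a joint fit, and median imputation
preserves the marginal location of each feature.

`optimalCutpoint()` dichotomizes the score the way cut-point optimizers
used in survival analysis do: candidates are the midpoints between
consecutive distinct scores, candidates leaving less than
`min_group_frac` (default 10%) of patients in either group are discarded,
and the cut-off minimizing the two-group log-rank p is selected (ties
toward the lower cut-off). Because a minimized p-value is optimistically
biased, the Miller–Siegmund corrected p is reported alongside; selection
itself still uses the raw minimum, mirroring standard cut-point-optimizer
behaviour. Patients with scores strictly above the cut-off form the
heterogeneous ("high") group; a score exactly at the cut-off is "low".

# Survival machinery

Kaplan–Meier estimation, the log-rank test, Cox fitting, the
proportional-hazards check and the categorical association tables are thin
wrappers over the `survival` package, pinned to explicit conventions: the
Efron approximation for tied event times, pooled risk sets in the log-rank
test, Wald inference, and a time-dependent-covariate PH check that
augments the model with `x · log(t)` (the time transform is configurable
to identity; the logarithm is the common default because hazard-ratio
drift is usually multiplicative in follow-up time). Tests in the package
verify these wrappers against independent hand computations — risk-set
products for KM, the O−E/V formula for the log-rank statistic, an
analytically solvable three-subject partial likelihood for Cox.

# The synthetic cohort generator

`generateCohort()` emulates the statistical structure the analysis
assumes, not histology. Each patient has a latent heterogeneity level
θ ∈ [0, 1] drawn from a Beta prior (default Beta(1.5, 1.5), so cohorts
contain both homogeneous and heterogeneous tumors).

*Spatial fields.* Patch labels for region, grade and pleomorphism come
from a hierarchical block-resampling process: at θ = 0 each class occupies
one contiguous block with exact proportions; a Bernoulli(θ) subset of
patches is then resampled with labels drawn on super-blocks whose side
shrinks from the spatial correlation length (default 62 µm) to a single
patch as θ → 1, where labels are i.i.d. We chose this over a Gibbs /
Markov-random-field sampler because the two limits are exact by
construction — a coupled MRF equilibrates to neither a deterministic
segregated layout nor exact i.i.d. labels — while intermediate θ still
interpolates through the correlation length. Region boundaries are
additionally warped by a smooth random displacement (±6 px, period 8 px):
patch-wise CNN predictions are patch-aligned, but region segmentations are
not, and perfectly patch-aligned regions would make region–region
colocalization degenerate.

*Nuclei.* Homogeneous Poisson placement within the permitted region
classes with class-specific densities; immune density is tripled in a
3-px band at the tumor–stroma interface so that intratumoral versus
stromal TILs layers are genuinely different. Densities (0.030 / 0.012 /
0.010 / 0.004 nuclei per label-map pixel for tumor / immune / connective /
normal-epithelial) give a few dozen nuclei per 62-µm patch in the
permissive regions, comparable to cellular densities in breast tissue at
this resolution.

*DCIS.* Random disc blobs covering ~4% of tissue by default — enough to
exercise the exclusion path on every map without modelling DCIS
morphology.

*Survival.* Event times are exponential with hazard
`baseline_hazard · exp(β_true · θ)` (defaults 0.01/month and β_true = 1),
censored independently at 0.003/month and administratively at 240 months;
these give a median follow-up around ten years and an event fraction near
80%, typical of long-follow-up breast-cancer cohorts.

*What passing tests do and do not show.* The generator produces spatially
clustered class fields, registered layers, realistic missingness and a
planted monotone θ–hazard link, so it validates the mechanics and the
statistical behaviour of the pipeline (feature monotonicity in θ, effect
recovery, screening size, cut-point optimism). It does not reproduce
H&E texture, nuclear morphology, inter-feature correlation structure of
real cohorts, or any cohort-specific quantity — numbers obtained on
synthetic cohorts say nothing about the values real slides would give.

# Numerical choices and degenerate inputs

* Coordinates are 0-based with the floor rule for down-sampling;
  rasterization is bit-exact under a fixed ordering.
* Co-occurrence accumulation is symmetric by construction; the matrix is
  normalized after the divide-by-two, so the two operations are kept even
  though normalization absorbs the halving.
* Ties in the dominant-level summary break toward the lower level; ties
  in the cut-point scan break toward the lower cut-off.
* Undefined statistics are `NA`, never zero, except colocalization of two
  empty layers and correlation of a constant map, which are defined as 0
  *and* flagged so callers can distinguish the convention from data.
* All randomness flows through one master seed; per-patient and
  per-purpose sub-seeds are derived arithmetically below 2³¹, so any
  patient's maps can be regenerated without generating the rest of the
  cohort.

# Validation problem sizes

The shipped test-suite exercises the pipeline at sizes chosen to balance
statistical resolution against desk-scale runtime: oracle equivalence on
all patch maps up to 5×5; screening size with 200 null features on a
500-patient cohort; effect recovery (±0.15 around β_true = 1) at
n = 1000; the end-to-end planted-effect analysis at n = 300; the
minimum-p optimism study with 500 simulated null cohorts of 100 patients;
and score–θ monotonicity on a 100-patient cohort. On cohorts this small,
univariate screening can legitimately retain nothing at α = 0.05;
`runPipeline()` then falls back to the five smallest-p features with a
warning rather than aborting a smoke run.

# Known limitations

* The feature catalogue is a reconstruction with the documented default
  composition; analyses comparing catalogues must export and version the
  YAML definition.
* The multivariate Cox step is not designed for feature sets approaching
  the event count; the ridge fallback makes it total, not optimal.
* The minimum-p cut-point is selected on the same cohort it is later
  tested on; the corrected p quantifies but does not remove that
  optimism. External validation of a fixed cut-off is out of scope.
* Single-slide patients only; multi-slide aggregation is not modelled.

# Session

```{r}
sessionInfo()
```
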