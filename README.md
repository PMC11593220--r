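# ithquant

Quantification of spatial intra-tumor heterogeneity (ITH) in breast-cancer
whole-slide analyses, starting from the label maps that segmentation
models produce: a region map (tumor / tumor-associated stroma / other), a
classified nuclei point set, patch-level digital grade and pleomorphism
maps, and a DCIS exclusion mask. The package is aimed at computational
pathology groups who have such maps and want a reproducible, configurable
ITH score with its downstream survival analysis.

## What it computes

Maps are tiled into 62-µm patches. For each analysis layer a normalized,
symmetric co-occurrence matrix *p(i, j)* is accumulated over the eight
unit-offset neighbour directions (counts halved so each unordered pair
counts once, then normalized to sum 1), and from it the Haralick-style
statistics

- contrast = Σ p(i,j) (i−j)², dissimilarity = Σ p(i,j) |i−j|,
- homogeneity = Σ p(i,j) / (1+(i−j)²), **heterogeneity = 1 − homogeneity**,
- correlation, uniformity = Σ p(i,j)², energy = √uniformity,
  entropy = −Σ p log₂ p,

plus the colocalization of layer pairs, Σₖ min(aₖ,bₖ) / Σₖ max(aₖ,bₖ).
The default catalogue is 18 layers × 8 statistics + 18 colocalization
pairs = **162 features per patient**, each assigned to a heterogeneity
family (differentiation, stroma, TILs). Features are min–max scaled to
0–100; family scores are the scaled member means; the **overall ITH
score** is `a + Σ bᵢ xᵢ` with multivariate Cox betas over the
univariately screened features, dichotomized at the cut-point minimizing
the two-group log-rank p (with the Miller–Siegmund min-p correction
reported). Kaplan–Meier / log-rank / Cox / PH-check / chi-square / ANOVA
wrappers round out the analysis. A synthetic cohort generator with a
controllable true heterogeneity level θ (and survival whose hazard rises
with θ) makes the whole pipeline testable end-to-end.

## Worked example

```r
library(ithquant)

params <- syntheticParams(n_patients = 100, seed = 31)
cohort <- generateCohort(params)

x  <- buildFeatureMatrix(cohort$stacks, cohort = cohort$cohort)
xs <- scaleFeatures(x)                       # 0-100 per feature
screened <- screenFeatures(xs, alpha = 0.05) # univariate Cox screen
model <- fitITHModel(xs, screened)           # multivariate Cox betas
cal <- calibrateCutoff(model, xs)            # min-p cut-point

cal$cutpoint
#> CutpointResult: cutoff 0.6794 (min p = 0.00204, corrected p = 0.046, 80 candidates)
table(cal$groups)
#>  low high
#>   79   21

logrankTest(cohort$cohort, cal$groups)$p
#> [1] 0.002038536
coxFit(data.frame(cohort$cohort,
                  high_ith = as.integer(cal$groups == "high")), "high_ith")
#> CoxFit: n = 100, events = 85, converged = TRUE
#>               beta        se       HR  lower95  upper95           p
#> high_ith 0.7808164 0.2594316 2.183254 1.313021 3.630253 0.002614888
```

Read: on this simulated 100-patient cohort the screened, Cox-weighted ITH
score splits patients at 0.679 into 79 low / 21 high; the high-ITH group
has a 2.2-fold hazard (95% CI 1.3–3.6), log-rank p ≈ 0.002 — and the
corrected cut-point p (0.046) shows how much of the raw minimum-p
significance is selection optimism. The score tracks the generator's true
heterogeneity level (Spearman ρ = 0.82 on this run).

`runPipeline(pipelineConfig(...))` runs the same stages end-to-end and
writes the feature matrix, family scores, model JSON, group labels, KM
curves and test tables into an output directory;
`inst/scripts/ith-quant.R` is a command-line front-end with
`simulate | features | score | survival | report | all` subcommands.

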