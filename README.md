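# layerdens

Density-based analysis of retinal layer thickness maps from optical
coherence tomography (OCT).

## The problem

Diabetic retinopathy alters the thickness of individual retinal layers,
and OCT segmentation delivers dense per-layer thickness maps of the
macula.  Conventional analyses collapse each map to scalar summaries
(mean thickness, quartiles) and lose the shape of the thickness
distribution.  `layerdens` is for researchers who want to use the *whole*
pixel-thickness distribution inside the ETDRS grid as the per-subject
data object — to classify disease groups, to average and visualise group
densities, and to test group differences — together with a calibrated
synthetic cohort generator so the full pipeline is runnable without
restricted clinical data.

## The method

For each subject and layer, the thickness values at non-missing pixels of
the 6 mm ETDRS disc are pooled and a kernel density estimate
f is computed on a shared unit interval.  Densities are embedded by the
square-root transform h = √f, a point on the positive orthant of the unit
Hilbert sphere in L²([0,1]), where the Fisher–Rao geometry reduces to
ordinary spherical geometry:

- geodesic distance d(h₁, h₂) = cos⁻¹ ∫₀¹ h₁(x) h₂(x) dx,
- group average = Karcher mean h̄ = argmin Σᵢ d(h, hᵢ)², with f̄ = h̄²,
- tangent PCA at h̄: scores X = VŨ from the SVD of the log-mapped sample,
  retaining components explaining 99.99% of variance.

The scores are Euclidean and feed a logistic regression
log(p/(1−p)) = xᵀβ, evaluated by leave-one-out cross-validation with
per-fold refitting of the transform, mean and PCA (no leakage).  Reports
give the AUC with a DeLong-variance Wald confidence interval at the
Bonferroni-corrected 98.3% level (three pairwise comparisons at overall
95%), sensitivity, specificity and the Brier score, next to a
five-number-summary baseline.  Group mean differences are tested by
permutation on d₀ = d(h̄⁰, h̄¹).

## Worked example

Generate the default synthetic cohort (41 controls / 28 NoDR / 38 NPDR,
inner-nuclear-layer tail masses above 50 µm calibrated to 0.29 vs 0.40)
and run one pairwise comparison end to end:

```r
library(layerdens)
cohort <- generate_cohort(cohort_config(seed = 42))
cfg    <- analysis_config(n_perm = 1000L, seed = 42)
res    <- run_pairwise(cohort, "INL", c("controls", "NPDR"), config = cfg)
print(res$report_density)
print(res$perm)
cat(sprintf("Karcher-mean mass above 50 um: controls %.1f%%, NPDR %.1f%%\n",
            100 * res$tail_mass[["controls"]], 100 * res$tail_mass[["NPDR"]]))
```

```
LOOCV classification report (density-based features)
  n = 41 + 38, AUC = 1.000, 98.3% CI (1.000, 1.000)
  sensitivity 1.000, specificity 1.000, Brier 0.000
Permutation test on geodesic distance between group means
  d0 = 0.1343 rad, 1000 permutations (conventional direction)
  p = 0 (adjusted 0)
Karcher-mean mass above 50 um: controls 27.6%, NPDR 38.0%
```

Reading the output: the cross-validated AUC and its 98.3% interval
exclude 0.5, so the inner nuclear layer separates the calibrated groups;
the permutation test finds the geodesic distance between the group mean
densities (0.134 radians) larger than every permuted distance; and the
tail masses recovered from the group Karcher means sit within the
kernel-smoothing tolerance of the generator's 29% / 40% targets.
Synthetic subjects differ only by pixel-sampling noise, which is why the
calibrated contrast separates perfectly — see the methods vignette
(`vignettes/density-geometry.Rmd`) for what that does and does not say
about real cohorts.  An uncalibrated null layer (`"NFL"`) gives an AUC
interval containing 0.5 and a large permutation p-value.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/layerdens-cli.R simulate --out cohort_dir --seed 1
Rscript inst/cli/layerdens-cli.R extract  --dir cohort_dir --out pixels.csv
Rscript inst/cli/layerdens-cli.R analyze  --dir cohort_dir --out reports
Rscript inst/cli/layerdens-cli.R report   --dir reports --out merged.csv
```

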