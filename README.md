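# t2nomo

Predicting the response of thyroid-associated ophthalmopathy (TAO) to
intravenous methylprednisolone (ivMP) from pre-therapy orbital MRI, using
volumetric T2 relaxation-time (T2RT) histogram features of the extraocular
muscles (EOMs). The package is aimed at quantitative-MRI and clinical
imaging researchers who want a fully scripted, testable version of this
analysis — from multi-echo voxels to a per-patient nomogram probability —
without access to patient data: a synthetic phantom generator stands in
for the cohort.

## What it computes

1. **Relaxometry** — voxel-wise mono-exponential T2 mapping,
   `S(TE) = S0 · exp(−TE/T2)`, from an 8-echo stack (TE 9.9–79.2 ms), by
   weighted log-linear least squares (default) or Levenberg nonlinear fit.
2. **Histogram features** — per orbit, the 12 volumetric first-order
   parameters of the pooled EOM VOIs: mean, SD, 5th–95th percentiles,
   skewness `μ₃/σ³`, kurtosis `μ₄/σ⁴`, entropy
   `−Σ pᵢ log₂(pᵢ+ε)` and inhomogeneity `Σ pᵢ²` over 1-ms histogram bins.
3. **Cutoff statistics** — rank-estimator AUC with DeLong CIs,
   Youden-index-optimal cutoffs (`J = sens + spec − 1`), strict `>`/`≤`
   dichotomisation, uncorrected χ² univariate screening, ICC(2,1) reader
   agreement.
4. **Model** — binary logistic regression (IRLS) with Wald CIs
   `exp(β ± 1.96·SE)`, a points-based nomogram (top predictor = 100
   points; total points map exactly to the logistic probability) and the
   apparent C-index.
5. **Phantom** — synthetic bilateral cohorts (default 45 patients, 90
   orbits) whose ground-truth T2 mixtures reproduce the reported group
   contrast (responders: lower 5th/10th percentiles; higher 75th/90th/95th
   percentiles, skewness, entropy, inhomogeneity), with Rician magnitude
   noise and NIfTI-1 + JSON-sidecar I/O.

See `vignettes/t2-histogram-nomogram.Rmd` for the model, conventions and
design rationale.

## Worked example

```r
library(t2nomo)

cfg <- phantom_config(seed = 1)                 # 45 bilateral patients
res <- run_pipeline(pipeline_config(phantom = cfg, write_nifti = FALSE),
                    "run1")

res$cutoffs$p95
#> p95: AUC 0.999 (0.998-1.000, p = 0); cutoff >100.8, sens 98.2%,
#>   spec 100.0%, Youden 0.982

res$model
#> Treatment-response nomogram
#>   retained predictors: p5, skewness, entropy
#>   note: full model separated; retained top 3 predictors by single-predictor LRT
#> Nomogram points (full predictor scale):
#>   p5                        100.0
#>   skewness                   87.7
#>   entropy                    71.7
#>   baseline probability (all zero): 0.0034
#>   apparent C-index: 0.963

head(res$scores[, c("patient_id", "side", "outcome",
                    "total_points", "probability")], 4)
#>   patient_id  side      outcome total_points probability
#> 1       P001  left   responsive    259.39350   0.9926703
#> 2       P001 right   responsive     87.66845   0.1095752
#> 3       P002  left unresponsive    187.66845   0.8790285
#> 4       P002 right unresponsive    100.00000   0.1690797
```

Reading the output: each orbit's dichotomised features earn nomogram
points; the total maps to the predicted ivMP response probability
(`P001 left`, with all three flags positive, scores 259 points ≈ 0.99;
an all-negative orbit sits at the 0.0034 baseline). The AUC row is one
line of the cutoff table written to `run1/cutoffs.csv`; note the full
11-flag model is completely separated at n = 90 orbits — it is reported
with that flag, and a parsimonious likelihood-ratio-ranked subset carries
the nomogram (vignette, "Separation").

The run directory also contains `features.csv` (90 orbit rows),
`univariate.csv` (dichotomised 2×2 counts and χ² p-values),
`model_full.csv`, `forest.csv`, `nomogram.json`, `scores.csv` and a
`manifest.json` stamped with the configuration hash; rerunning the same
configuration reproduces every file byte-identically.

A thin command-line wrapper over the same functions is at
`inst/cli/t2nomo.R` (`simulate`, `fit-t2`, `features`, `cutoffs`, `model`,
`score`, `run`).

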