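---
title: "Methods: T2 relaxometry histogram features and the treatment-response nomogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: T2 relaxometry histogram features and the treatment-response nomogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(t2nomo)
```

## The problem

In thyroid-associated ophthalmopathy (TAO), intravenous methylprednisolone
(ivMP) is the first-line treatment of active moderate-to-severe disease, but
a substantial fraction of patients does not respond. The extraocular muscles
(EOMs) are the main orbital target tissue, and their voxel-wise T2
relaxation time (T2RT) reflects the underlying pathology: interstitial
edema and glycosaminoglycan deposition prolong T2, while fibrotic
remodelling shortens and homogenises it. The working hypothesis behind this
package is that the *distribution* of T2 within the muscles — not just its
mean — carries predictive information: a muscle that is mostly normal but
carries focal edema (an upper T2 tail) is inflamed and steroid-responsive,
whereas a diffusely remodelled muscle is not.

`t2nomo` implements the complete analysis that turns a pre-therapy
multi-echo orbital MRI into a per-patient predicted response probability:

1. voxel-wise mono-exponential T2 mapping from an 8-echo acquisition,
2. volumetric first-order histogram features of the EOM VOIs,
3. Youden-index cutoff selection and dichotomisation,
4. chi-squared univariate screening,
5. multivariate binary logistic regression with a points-based nomogram
   and an apparent C-index.

Because no patient data are distributable, the package ships a synthetic
phantom generator whose cohorts have the statistical structure the analysis
assumes, so that every stage is testable end to end.

## Relaxometry

The signal model is mono-exponential, $S(TE) = S_0 e^{-TE/T_2}$, with the
acquisition's echo train (eight echoes, $TE = 9.9$–$79.2$ ms,
$\Delta TE = 9.9$ ms) as the default. Two estimators are provided:

* `loglinear_wls` (default): weighted least squares of $\log S$ on $TE$
  with weights $S^2$. These are the delta-method weights under
  constant-variance signal noise, the fit is closed-form, deterministic and
  vectorised over voxels.
* `nls`: Levenberg–Marquardt minimisation of the signal-domain sum of
  squares, initialised from the log-linear solution. Useful in the
  low-SNR magnitude (Rician) regime; on noiseless data both estimators
  agree to $10^{-6}$ ms.

Numerical rules: a single nonpositive echo (possible in magnitude data
after subtraction or in background) is dropped when at least three points
remain; two or more nonpositive signals invalidate the voxel. Fits are
accepted only inside a T2 window of $[1, 500]$ ms — wide enough for any
orbital tissue, narrow enough to keep divergent fits out of the
histograms. No spatial regularisation is applied.

A useful calibration point: at SNR 30 with this echo train, the
Cramér–Rao bound for $T_2 = 110$ ms is $\sigma \ge 9.5$ ms, so per-voxel
errors of several milliseconds at long T2 are physics, not implementation;
the test suite checks the estimator sits within 15% of the bound.

## Histogram features

For each orbit the five muscle VOIs (the superior rectus and levator are a
single "superior group" label) are pooled volumetrically by default and
summarised by twelve parameters: mean, SD, the 5th/10th/25th/50th/75th/90th/
95th percentiles, skewness, kurtosis, entropy and inhomogeneity.

Conventions, fixed so every number is reproducible:

* Percentiles use inclusive linear interpolation (order-statistic index
  $(n-1)q/100$, `quantile` type 7).
* Moments use population ($1/N_p$) normalisation: skewness $\mu_3/\sigma^3$,
  kurtosis $\mu_4/\sigma^4$ (normal $\to$ 3). Because a kurtosis *cutoff*
  near 0.6 in the reference literature suggests the excess convention was
  used there, an excess column (kurtosis $-$ 3) is also emitted.
* Entropy is $-\sum_i p_i \log_2(p_i + \varepsilon)$ with
  $\varepsilon = 2.2\times10^{-16}$, and inhomogeneity (energy/uniformity)
  is $\sum_i p_i^2$, both over the occupied bins of a fixed-width histogram
  anchored at 0. The bin width defaults to 1 ms — T2 is already in physical
  units — and is a configuration knob recorded in the output.

Three VOI-aggregation rules are provided because published practice is
ambiguous about whether per-orbit features come from one muscle or all:
`pooled_all_eoms` (default), `per_muscle`, and `max_mean_muscle`, the last
being a reproducible surrogate for "the most inflamed muscle" (the muscle
with the highest mean T2). None of the three is claimed to replicate any
specific manual protocol.

## Cutoffs, univariate tests, model, nomogram

AUCs use the rank (Mann–Whitney) estimator with half credit for ties;
confidence intervals use DeLong's variance of the paired placements. The
Youden cutoff scans every midpoint between adjacent distinct scores,
maximises $J = \text{sens} + \text{spec} - 1$, chooses the direction that
puts the responsive-enriched side on the positive side, and breaks ties
toward the smallest cutoff. Dichotomisation is strict: `>` cutoff for
"greater" features, `<=` for the others.

Univariate screening uses the uncorrected Pearson chi-squared (a Yates
flag exists; group sizes here are moderate). Features significant at
$p < 0.05$ enter a multivariate binary logistic regression fitted by IRLS,
with Wald 95% CIs $\exp(\beta \pm 1.96\,SE)$. Predictors retained at Wald
$p < 0.05$ are refitted and turned into a nomogram by the standard points
construction: predictor $i$ contributes up to
$100\,\beta_i r_i / \max_j \beta_j r_j$ points, and the total-points axis
maps to probability through the fit's own linear predictor, so nomogram
scoring and direct logistic evaluation agree to $10^{-9}$ by construction.
The C-index (= AUC for a binary endpoint) is apparent/in-sample; no
validation split is modelled.

**Separation.** With many strong, mutually correlated binary flags and 90
orbits, complete separation of the full model is not an edge case — on
synthetic cohorts it is the norm. No shrinkage is applied silently.
Instead, the full fit is always reported with a separation flag, and when
it is separated the retained subset is chosen as the top three predictors
by single-predictor likelihood-ratio $\chi^2$ (candidates restricted to
flags with all four 2x2 cells occupied, which guarantees a finite
single-predictor MLE), shrinking the subset until the refit converges.
A fit is treated as boundary/degenerate when any $|\beta| > 12$ or any
$SE > 100$ — far outside what finite, overlapping binary data produce.

Reader agreement is available as ICC(2,1) (two-way random effects,
absolute agreement, single measure; ICC(3,1) as an option) from the
explicit mean-squares decomposition.

## The synthetic cohort generator

The generator is the package's definition of the study conditions: 45
bilateral patients (90 orbits), responder fraction $24/45$, eight echoes,
Rician magnitude noise, five box-shaped muscle VOIs of 45 voxels per orbit
on a fixed 22x14x8 template (axis-aligned geometry only — features depend
only on value distributions, so no anatomical realism is attempted).

Ground-truth voxel T2 in each orbit is drawn from a three-component
mixture, truncated at positive values:

* a **base** component of normal muscle tissue,
  $N(68, 10 \cdot s_g)$ ms with $s_g = 0.2$ for responders and $1$ for
  non-responders,
* an **elevated tail** (focal edema), $N(68 + 30, 16)$ ms, with mean
  weight 0.30 in responders vs 0.02 in non-responders,
* a **low-T2 shoulder** (fibrotic strands), $N(68 - 22, 9)$ ms, with mean
  weight 0.22 vs 0.02.

The rationale: active, steroid-responsive disease is *focal* pathology on
mostly normal muscle — a tall narrow normal peak (which raises
inhomogeneity $\sum p_i^2$), flanked by an edema tail (raising the high
percentiles, skewness and entropy) and a fibrotic shoulder (lowering the
low percentiles). Chronic non-responsive disease is *diffuse* moderate
remodelling — one broad mid-T2 distribution. This is the only
three-component structure we found that reproduces all eight reported
contrast directions simultaneously (responders: lower 5th/10th
percentiles; higher 75th/90th/95th percentiles, skewness, entropy and
inhomogeneity); a plain two-component "base + heavier upper tail" model
cannot, since extra upper-tail mass necessarily raises the low percentiles
and spreads the histogram, lowering $\sum p_i^2$. The literature quantifies
none of these distributions, so the mixture parameters are documented free
knobs, chosen once on this biophysical reasoning and for robustness of the
eight directions, and recorded as defaults.

Biological variability enters through per-orbit mixture weights (Beta
distributed around the group means, concentration 30) and per-patient /
per-orbit jitter of the base mean (SD 3 and 2.5 ms), so orbit-level
features overlap between groups instead of separating trivially. SNR
defaults to 100 (first-echo muscle signal), appropriate for a 3T, 256
matrix, ~6-minute acquisition; at that level the T2 fitting noise (~1.4 ms)
does not wash out the narrow responder base component.

Outcome labels are generated by simulating per-eye therapy deltas whose
improvement probabilities depend on the latent group and passing them
through the three-major/six-minor response classifier (at least one major
or two minor criteria in any eye), so labels and criteria are mutually
consistent by construction. Clinical covariates (age, gender, thyroid
status, TRAb, CAS, duration, proptosis, intraocular pressure) are drawn
from cohort-level marginals typical of active moderate-to-severe TAO and
carried through the I/O layer.

All randomness flows from one integer seed through a counter-based
substream per patient, making cohorts bit-reproducible and individual
patients reproducible independently of cohort size.

### What the phantom does and does not emulate

It emulates: the group contrast directions, magnitude-MRI noise including
its low-SNR bias, VOI-based volumetric pooling, bilateral patients with
within-patient correlation, and label/criteria consistency. It does not
emulate: orbital anatomy, partial-volume contamination at muscle
boundaries, motion or fat-suppression artifacts, slice gaps, or
reader-dependent ROI placement. Passing tests on the phantom therefore
demonstrate correctness of the computations and internal consistency of
the pipeline — not clinical performance on real data. In particular the
apparent C-index on synthetic cohorts (typically 0.85–0.96) reflects the
configured contrast strength, and no claim is made that it reproduces any
real-cohort discrimination.

## Numerical choices and degenerate inputs

* T2 acceptance window $[1, 500]$ ms; invalid voxels are excluded from
  features; an all-invalid VOI raises an error naming the orbit and muscle.
* Constant-T2 VOIs: entropy $\to -\log_2(1+\varepsilon) \approx 0$,
  inhomogeneity $= 1$, all percentiles equal; skewness/kurtosis are
  undefined (zero variance) and returned as `NA` with a
  degenerate-distribution warning.
* Youden ties break toward the smallest cutoff, and toward the "greater"
  direction between equal-J directions.
* IRLS runs with tolerance $10^{-12}$ so converged fits satisfy the score
  equations to $10^{-8}$.
* Pipeline tables are stamped with an MD5 hash of the configuration;
  mixing stages from different runs is rejected.

## Problem sizes used by the test suite

The suite exercises: oracle equivalence on 1000-instance random families
(percentiles, AUC/C-index, Youden cutoffs), a $10^5$-draw permutation null
for the chi-squared test, logistic parameter recovery at $n = 10^5$,
$10^4$-voxel relaxometry recovery against the Cramér–Rao bound, and 100
seeded replicates of a 200-orbit cohort for the contrast-direction check.
These sizes keep the full suite within a few minutes on one CPU while
leaving Monte-Carlo margins comfortably wide.

## Known limitations

* The mono-exponential model ignores multi-compartment relaxation,
  stimulated echoes and B1 effects; at low SNR the Rician floor biases long
  T2 upward even with the weighted fit.
* Orbits are treated as independent units ($n = 90$), replicating common
  practice despite bilateral correlation; a patient-level cluster bootstrap
  would be the conservative alternative.
* The C-index is apparent; with separation-prone designs it overstates
  generalisable discrimination.
* Entropy and inhomogeneity depend on the histogram bin width; 1 ms is a
  documented default, not a standard.
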