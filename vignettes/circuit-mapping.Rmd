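---
title: "Mapping causal brain circuits from lesions and stimulation sites"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping causal brain circuits from lesions and stimulation sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

Focal brain perturbations — strokes and penetrating injuries, TMS to
varying scalp locations, DBS fields around an electrode — are natural
experiments: if perturbing a site changes a symptom, the site is causally
upstream of that symptom. Individual sites are scattered and small, so the
unit of analysis is not the site itself but its *network*: the whole-brain
functional connectivity profile of the site in a resting-state connectome.
This package implements that logic end to end for an anxiety-like outcome
measured alongside a depression confound.

The pipeline, per dataset:

1. **Perturbation model.** Lesions are binary masks (lesion size in voxels
   is retained as a covariate). TMS sites are decaying spheres: weight
   $w(v) = \max(0, 1 - d(v, c)/r_{\max})$ with $r_{\max} = 12$ mm. The
   decay law is not specified beyond "decaying sphere" in the tradition
   this follows; linear decay to zero is the simplest monotone profile with
   compact support and is isolated in one swappable function
   (`tms_site()`). DBS patients carry *two* binary fields (left/right),
   which are never merged into one seed.
2. **Seed connectivity.** For each connectome subject, Pearson r between
   the site's weight-averaged time-series and every in-mask voxel, clipped
   to $\pm(1 - 10^{-7})$, Fisher-transformed ($z = \mathrm{atanh}\, r$),
   then averaged across subjects. Clipping keeps z finite; z-before-average
   is the standard variance-stabilized estimator.
3. **Circuit map.** At each voxel, the partial correlation across patients
   between $z_i(v)$ and the outcome, controlling for the modality's
   covariates — depression plus baseline severity for stimulation
   (outcomes are changes), depression plus lesion size for lesions
   (outcomes are severities). Implemented as Pearson correlation of OLS
   residuals with an intercept, which matches the precision-matrix
   definition to 1e-10 (tested against that oracle).
4. **Combination.** Weighted mean of dataset maps with weight = dataset n,
   the only dataset-level weight reported in this literature; combination
   is associative when intermediate weights are carried. Leave-one-dataset-
   out rebuilds keep all evaluation out-of-sample.
5. **Inference.** All significance is by outcome shuffling: each patient's
   (outcome, covariates) tuple is re-assigned to another patient's imaging
   *within* dataset (outcome scales differ across datasets), every circuit
   map is rebuilt, and the statistic recomputed. P-values use the add-one
   form $(1 + \#\{\text{null} \ge \text{obs}\})/(1 + N)$ — one-sided,
   never exactly zero, slightly conservative.
6. **Validation.** New TMS/lesion sites are scored by spatial correlation
   of their connectivity map with the circuit; DBS pairs by overlap: mean
   circuit value under the left field plus mean under the right, an empty
   hemifield contributing zero (the natural extension of the additive
   formula to unilateral cases). Scores predict outcomes by partial
   correlation with a parametric two-sided p from the t-transform.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| TMS `max_radius_mm` | 12 | mm | conventional decaying-sphere extent |
| r clip | 1 - 1e-7 | — | finite Fisher z at |r| = 1 |
| `n_permutations` | 10000 | — | standard protocol; tests use 200 for speed |
| VLSM `min_lesions_per_voxel` | 5 | patients | keeps single-patient voxels from dominating |
| `top_fraction` (circuit poles) | 0.10 | — | within-circuit scoring uses the strongest decile per pole |
| pole subsample cap | 500 | voxels | bounds pairwise-correlation cost deterministically (seeded) |
| binarized-outcome thresholds | 1, 3 | points | categorical worsening analyses reuse the same partial-correlation primitive |

Every stochastic operation takes an explicit `rng_seed`, restores the
caller's RNG state, and records the seed in its result; identical seeds
give bitwise-identical null samples.

## The synthetic world

The generator (`synthetic_spec()`, defaults in parentheses) is a stated
world, not a tuning knob:

- **Grid**: 16³ voxels at 2 mm, spherical brain mask — small enough that a
  full pipeline run with hundreds of permutations takes seconds on one CPU.
- **Circuit**: signed Gaussian bumps (one positive pole at (6,6,6) mm, one
  negative at (−6,−6,−6), sd 6 mm), max |value| normalized to 1.
- **Connectome** (20 subjects × 100 timepoints): per subject, voxel series
  are spatially smoothed white noise (Gaussian kernel sd 4 mm, normalized
  to unit voxel variance including at the mask edge) plus one shared latent
  loading $\lambda c(v)$ with $\lambda = 1$, so the two poles are
  anticorrelated and circuit-adjacent seeds reproduce the circuit.
- **Cohorts** (n = 100): lesions are random 3–10-voxel blobs, TMS sites sit
  on the cortical shell, DBS pairs are mirrored deep fields of 2–4 voxels.
  The outcome is $y_i = \beta \tilde s_i + \gamma d_i + \sigma
  \varepsilon_i$ with $\beta = 0.5$, $\sigma = 1$, $\tilde s_i$ the
  standardized true score and $d_i \sim N(0,1)$ the latent depression,
  recorded as the depression covariate.
- **True scores** are computed from the generator's covariance analytically
  (the smoothing operator applied twice gives the noise covariance exactly),
  not from finite-sample seed maps: generative truth stays separate from
  estimation error, so recovery targets are meaningful.

Two design points deserve emphasis.

*The confound coefficient is solved, not sampled.* The target
anxiety–depression correlation is $\rho = 0.53$, the pooled value in the
clinical literature this emulates. A naive recipe — fix the depression
coefficient at $\rho$ and then add noise to the recorded depression —
cannot reach 0.53, because with $\beta = 0.5, \sigma = 1$ the implied
correlation is already 0.43 before any noise is added and extra noise only
lowers it. We therefore solve
$\gamma^2 = \rho^2 (\beta^2 + \sigma^2)/(1 - \rho^2)$, which makes
$\mathrm{corr}(y, d) = \rho$ exact in expectation with the latent recorded
directly; the empirical correlation lands within ±0.1 of 0.53 at n = 300
(tested).

*Site placement is independent of outcome.* Depression confounds the
outcome but not the site location, mirroring the as-if-random assumption
that pre-existing symptoms do not determine where a lesion lands.

What a green test does establish: unbiased machinery, calibrated
permutation nulls, recoverability of a planted circuit at stated effect
sizes. What it does not: realistic lesion anatomy (no vascular
territories), realistic BOLD spectra, scanner effects, or the clinical
effect sizes of real cohorts — the headline numbers of the motivating
studies depend on non-redistributable imaging and are out of desk-scale
reach by design.

## Numerical choices and edge cases

- Non-finite voxels are forced outside the analysis mask at construction;
  correlations never see NaN.
- Zero-variance voxels inside a seed map contribute z = 0 (no signal)
  rather than NaN; zero-variance *seeds* skip that subject with a warning
  and error only if no subject remains.
- Degenerate designs (constant outcome, covariate collinear with the
  predictor, condition number > 1e8 in specificity models) are hard
  errors, not silent zeros.
- Clusters use 26-connectivity with value-weighted centres of gravity — a
  generic stand-in for FSL-style cluster reporting.
- Grids must match exactly (shape, affine to 1e-6); there is no implicit
  resampling or axis flipping, the NIfTI affine is authoritative, and voxel
  indices are 0-based.
- The FWE peak test is max-statistic and one-sided. When the tested peak
  is *localized from the observed map* (the real workflow: find cluster
  peaks, then test), its null p-distribution is uniform, and the
  acceptance suite verifies this. Testing a fixed arbitrary voxel against
  the max-statistic null is valid but conservative. Negative-pole peaks
  are tested on the sign-flipped outcome scale.
- Permutation shuffles move the whole (outcome, covariates) tuple. Whether
  covariates should travel with the outcome is ambiguous in the tradition;
  tuple shuffling preserves the within-patient covariate structure and
  keeps the null honest when covariates correlate with the outcome.

## Known limitations

No registration or resampling (inputs must share a grid); no fMRI
preprocessing (time-series are consumed clean); no electric-field models of
TMS coils or electrode biophysics (sites and fields are consumed as masks);
no spatial-autocorrelation-preserving ("spin") nulls — the outcome-shuffle
null preserves the imaging exactly but not map smoothness under map-to-map
comparisons of *independent* maps; and inverse-variance weighting of
dataset maps is not implemented because n-weighting is what the tradition
reports (the `weight` field is user-settable where a different scheme is
wanted).
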