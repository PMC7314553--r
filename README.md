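# lamsurf

Depth-resolved (laminar) fMRI analysis of visual surface perception, as an R
package.

## The problem

When a uniform surface is perceived — and especially when an illusory percept
such as surface motion is induced — early visual cortex (V1/V2/V3) responds
with a characteristic spatial and laminar signature: a *negative* sustained
BOLD response at the retinotopic representation of the surface interior
(relative to a textured-background baseline), a *positive* transient response
at the representation of the surface edge, and a small condition-specific
signal increment (on the order of 0.3% signal change) whose cortical depth
profile carries information about feedback vs. feedforward processing.
Measuring that depth profile at sub-millimetre resolution requires a chain of
specialised steps, each of which this package implements as a tested,
reusable component:

- **Stimulus construction** — rotating sector-cut disk ("Pac-Man"), static
  control, and dynamic wedge control aperture movies whose left visual
  half-field is pixel-identical across conditions; block-design run
  schedules (16 blocks of 10.4 s, counterbalanced variable rests, 250
  volumes at TR 2.079 s); fixation-target events decorrelated from the
  stimulus predictor (|r| < 0.001); background textures and the display's
  cubic pixel-to-luminance calibration.
- **pRF mapping** — Gaussian population receptive field estimation by
  exhaustive grid search from bar-aperture runs (4 orientations x 8
  positions = 32 configurations), yielding per-unit (x0, y0, sigma, R^2)
  and eccentricity/polar-angle maps.
- **GLM** — sustained (boxcar) plus transient (onset/offset delta)
  predictors per condition, double-gamma HRF, discrete-cosine high-pass
  filtering (cutoff 35 s), and conversion of betas to percent signal change
  relative to the initial 20.8 s pre-stimulus baseline.
- **Laminar geometry** — equi-volume cortical depth levels (10 compartments,
  11 boundaries; closed forms for flat, annular, spherical column
  geometry), depth sampling, and quantitative ROI selection (median
  R^2 > 0.15, minimum EPI intensity >= 7000, eccentricity bands 1–3 deg
  centre / 3.5–4 deg edge; all-or-none per cortical segment).
- **Draining-vein deconvolution** — a lower-triangular leakage model
  `observed = W · local` for the pial-ward venous bias of gradient-echo
  BOLD, inverted by sequential forward substitution from the deepest level
  upward.
- **Visual-field projection** — per-unit statistics projected into visual
  space as the pRF-density-normalised weighted mean
  `V_ij = Σ_k M_ijk p_k / Σ_k M_ijk`, with subject pooling by concatenation
  before normalisation.
- **Group statistics** — condition contrasts over depth, response-onset
  detection (one-sample t-tests, Bonferroni), superficial-peak
  classification (global maximum within the upper third of grey matter) with
  chi-squared comparison between areas, and likelihood-ratio tests between
  nested linear mixed-effects models (random depth slope per subject,
  continuous-AR(1) residual correlation over depth, ML fits via nlme).
- **Synthetic data** — a ground-truthed cortical phantom (lattice of columns
  x depth levels with programmed retinotopy, laminar amplitudes, EPI
  intensities and leakage) so the entire chain is testable end to end
  without any real acquisition.

## Worked example

```r
library(lamsurf)

report <- run_pipeline(pipeline_config(n_subjects = 10, seed = 1,
                                       phantom_args = list(n_ecc = 8,
                                                           n_angle = 4)))
print(report)
#> pipeline_report: 10/10 subjects kept, peak depth 0.20 (superficial)

round(report$local_contrast$mean, 3)
#>  [1]  0.064  0.194  0.287  0.268  0.175  0.066  0.036 -0.007  0.017 -0.014
#> [11]  0.008
```

The phantom programs a +0.3% sustained increment for the motion-induction
condition, peaking at 25% cortical depth in V1, on top of a -2.5% interior
response, with draining leakage (lambda = 0.3), 0.5% noise and 10% between-
subject amplitude variability. The pipeline simulates ten subjects, fits the
GLM per voxel, averages percent signal change over the selected centre-band
ROI per depth, forms the per-subject motion-minus-dynamic contrast, and
deconvolves the draining bias. The printed profile (pial surface first) peaks
at depth fraction 0.20 — within one depth level of the programmed 25% — with
amplitude 0.287%, matching the programmed increment sampled on the 11-level
depth grid (0.284%).

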