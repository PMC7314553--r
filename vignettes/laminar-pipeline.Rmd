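---
title: "Depth-resolved analysis of surface-perception fMRI: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved analysis of surface-perception fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lamsurf)
```

This vignette explains the models implemented in `lamsurf`, the assumptions
behind them, the parameters that matter, and the design decisions taken where
more than one reasonable implementation existed. The package analyses
laminar (cortical-depth-resolved) fMRI from block-design visual
surface-perception experiments, and ships a ground-truthed synthetic
generator so that every stage can be validated against known truth.

## Stimulus and design model

Three aperture movies define the main experiment: a sector-cut luminance
disk (7.5° diameter, 70° removed sector) whose sector oscillates
sinusoidally, θ(t) = A·sin(2πft) with A = 35° and f = 0.85 Hz (the
motion-induction condition); the same disk frozen at θ = 0 (static control);
and a stationary 220° left wedge plus a 65° right wedge following the same
sinusoid (dynamic control). Because the removed sector and the rotating
wedge stay within ±67.5° of the right horizontal meridian, the left
half-field image is constant over time and pixel-identical across the three
conditions — the property that licenses attributing left-hemifield response
differences to perceptual rather than retinal factors. Rasterisation marks a
pixel occupied when its centre lies inside the shape, with no anti-aliasing:
binary apertures keep the pRF forward model a plain weighted sum. The frame
rate defaults to 30 frames/s (display hardware is out of scope, so this is
only a sampling density for the movies); the default grid is 0.05°/pixel.

Runs follow a fixed arithmetic: 16 stimulus blocks of 5 TRs (nominally
10.4 s at TR = 2.079 s) alternate with 17 rests — a fixed 10-TR initial rest
and 16 variable rests of 9, 10 or 11 TRs. The variable rests are
counterbalanced with counts as equal as possible (5/6/5, remainder to the
middle duration) and shuffled by seed; this is the only assignment that
reproduces the printed run totals of 250 volumes ≈ 520 s. Durations given in
rounded seconds are snapped to the nearest integer TR count (tolerance
0.06 s); schedules store exact TR multiples.

Fixation-target events (0.8 s, mean ITI 30 ± 10 s, none in the first or
last 15 s) are placed by rejection sampling until the Pearson correlation
between the HRF-convolved stimulus and target predictors is below 0.001 in
absolute value, with a hard iteration cap (default 10^5) and the achieved
correlation stored for independent re-verification. Background textures draw
i.i.d. Gaussian intensities (mean 40, SD 60 in 8-bit units), clip to
[0, 255], then apply a 6×6 uniform box filter; clipping before filtering is
the default (the alternative order is available) because the display
receives clipped values. The display calibration is the fixed cubic
y = −78.8x³ + 78.7x² + 317.2x + 163.3 cd/m².

## Haemodynamic and GLM model

The HRF is the canonical double gamma (peak 6 s, undershoot 16 s, unit
dispersions, undershoot ratio 1/6), sampled at the TR and peak-normalised.
Each condition contributes two regressors: a sustained predictor (boxcar
over the block convolved with the HRF) and a transient predictor (unit-area
deltas at block onset and offset sharing one beta). Convolution is done on a
fine grid (TR/20) and sampled at volume onsets. High-pass filtering uses a
discrete-cosine drift basis at the 35 s cutoff, applied identically to data
and regressors; a projection was chosen over a running-line filter because
it is exactly idempotent, which makes the filtering algebra (and its tests)
exact. No prewhitening is applied at the run level; serial dependence is
handled at the group level, where inference actually happens.

Betas are converted to percent signal change as 100 × beta / mean(raw signal
over the initial 20.8 s pre-stimulus window). Task regressors are
peak-normalised to 1, so a beta equals the peak response amplitude in raw
signal units and the PSC of a simulated amplitude round-trips exactly; the
synthetic generator uses the same regressor construction, which is what
makes the noiseless phantom→GLM→PSC chain exact to numerical precision
rather than approximate. Differential contrasts are PSC differences.
Event-related averages cut peri-onset windows per block, express each
segment as PSC relative to the pre-block mean (default two volumes), and
average over repetitions, then subjects.

## pRF model

A unit's population receptive field is an isotropic 2D Gaussian (x0, y0,
σ). The predicted response to an aperture movie is the per-volume spatial
overlap Σ_pixels aperture × Gaussian, HRF-convolved, with free amplitude.
Fitting is an exhaustive grid search (defaults: x, y from −4° to 4° in
0.25° steps; six log-spaced σ between 0.2° and 2°), selecting the
candidate maximising R²; amplitude comes from least squares with intercept.
Ties break toward smaller σ, then smaller eccentricity; zero-variance time
courses are flagged rather than fitted. Grid search without subsequent
nonlinear refinement keeps results deterministic and testable; the candidate
prediction matrix is precomputed once and reused across units, which is what
makes fitting 200 units a few-second operation. Bar runs present each of
the 32 configurations (4 orientations × 8 positions, 1.25° width) for one
TR in seeded random order, 12 repetitions, with explicit rest padding
(default 8 volumes at each end) — the padding is a free parameter because
the run length bookkeeping of the original design leaves it unspecified.

## Equi-volume depth levels and ROI selection

Cortical depth is expressed as a fraction from the pial surface (0%) to the
white/grey-matter boundary (100%). Ten compartments yield eleven boundary
depths. On curved geometry the boundaries equalise compartment volume: for
an annular column r_j = √(r_wm² + (j/n)(r_pial² − r_wm²)), and
correspondingly with cubes for spherical shells; flat geometry reduces to
equidistant spacing. The package models each column's geometry
parametrically (flat by default) rather than meshing real anatomy — mesh
machinery is out of scope, and the parametric forms carry the entire
algorithmic content with closed-form tests.

ROI selection is quantitative and all-or-none per cortical segment: median
pRF R² over depths > 0.15, minimum mean-EPI intensity over depths ≥ 7000
(vein/sinus exclusion; the threshold is a configuration default since
intensity units are scanner-specific), and median eccentricity within the
band (centre 1–3°, edge 3.5–4°).

## Draining-vein model and deconvolution

Ascending veins carry deoxygenation changes pial-ward, so observed
gradient-echo profiles are biased toward the surface. The model is linear:
`observed = W · local` with W lower-triangular in deep-to-superficial
ordering and unit diagonal. The shipped default is a cumulative drain in
which a fraction λ (default 0.3) of each depth's signal is added to every
more superficial depth; λ is configurable and any full weight matrix can be
loaded from TSV, because published leakage weights vary between vascular
models and the default should be read as an approximation, not a
measurement. Deconvolution proceeds by forward substitution from the deepest
level upward — subtracting the estimated contribution of all deeper levels —
which is algebraically the triangular solve of W·x = observed; the tests
assert both the equivalence and round-trip inversion to 1e-12. Internally
depth index 1 is the white-matter boundary; display order (pial first) is an
explicit conversion, because mixing the two silently is the classic bug of
this analysis.

## Visual-field projection

Unit statistics are projected into visual space as
V_ij = Σ_k M_ijk p_k / Σ_k M_ijk, with M_ijk the unit-height Gaussian pRF of
unit k evaluated at pixel (i, j). The projection is a pRF-density-normalised
weighted mean, hence bounded by the extremes of p (a convexity property the
tests assert) and exactly constant for constant p. No smoothing is applied.
Pixels whose density falls below 1% of the peak are masked — the normalising
denominator is meaningless where no pRF covers the location; the floor is
reported with the output. Multi-subject projections concatenate all
subjects' (model, statistic) pairs before normalisation; this is not the
mean of per-subject projections (the package includes a constructed
counterexample demonstrating the difference).

## Group statistics

Condition contrasts are formed per subject per depth, then summarised as
group mean ± SEM. Response onsets are detected per time point with
two-sided one-sample t-tests against zero across subjects at a
Bonferroni-corrected threshold (family = number of in-window time points);
two-sidedness matters because edge responses are positive while interior
responses are negative. Peak depth is the global maximum of a contrast
profile; a peak is superficial if within the upper third of grey matter;
exact ties break toward the more superficial depth (a documented choice —
the alternative is equally defensible and isolated in one place).
Superficial-peak proportions are compared between areas with Pearson's
chi-squared test without continuity correction.

The mixed-model layer fits percent signal change with fixed factors area,
condition and depth plus all two-way interactions, a random depth slope per
subject, and continuous-AR(1) residual correlation over depth; because the
CAR(1) index must be unique within its grouping, correlation groups are the
depth series within each subject × area × condition cell. Models are fitted
by maximum likelihood (not REML — the compared models differ in fixed
effects) with `nlme`, and nested pairs are compared by likelihood-ratio
test. The optimiser falls back from `optim` to `nlminb` before reporting
non-convergence; in the 500-replicate null calibration this affects a
handful of hard surfaces and leaves the type-I error rate within the
expected band around 0.05.

## Synthetic data: what it emulates and what it does not

The phantom is a lattice of cortical columns × depth levels per area
(V1/V2/V3), with a smooth eccentricity × polar-angle retinotopy over the
right hemifield, pRF width growing linearly with eccentricity
(σ = 0.2° + 0.1°·ecc), and mean-EPI intensities around 10,000 with a mild
superficial gradient, 10% static voxel-wise tissue contrast, and optional
sub-threshold columns to exercise the intensity exclusion. Programmed
responses: −2.5% sustained in the centre band for all conditions (the
negative-interior response, generatively an elevated textured-background
baseline minus the figure response), +1.5% transient at the edge band, and
a +0.3% sustained increment for the motion condition only, shaped as a
Gaussian bump over depth centred at 25% with width 0.15 in V1. Noise is
AR(1) (coefficient 0.3) plus white noise (0.5% of baseline) and a slow
cosine drift (0.5%), with multiplicative subject amplitude scaling
(SD 10%); this is the minimal model that exercises high-pass filtering,
GLM noise propagation and between-subject variance, chosen because no noise
specification accompanies the original acquisition. The simulator passes
laminar truth through the same leakage forward model the analysis inverts,
and builds the response with the same regressors the GLM uses — so
noiseless runs round-trip exactly, which is the intended validation
property, not an accident.

What the phantom does *not* emulate: physiological noise structure, motion,
distortion, depth-dependent SNR gradients of gradient-echo acquisitions
(parameterisable but defaulting to depth-constant noise), partial-volume
mixing between depths, and real cortical folding. Passing tests therefore
demonstrate the correctness of the algorithms under the stated generative
model, not the robustness of the full chain to real-data artefacts.

## Numerical choices and problem sizes

Convolution quadrature uses a TR/20 grid; equi-volume and deconvolution
identities are closed-form and tested at 1e-12; PSC round-trips are exact
to ~1e-8 (limited by convolution quadrature, not algebra). The shipped
validation runs use: 1000 random leakage models for the deconvolution
oracle; 200 pRF units at SNR 10 (median eccentricity error ~0.06°, well
under the 0.25° grid step); an end-to-end phantom with 8 × 4 columns per
area, 11 depths, 10 subjects; and 500 replicates for the null calibration
of the likelihood-ratio test with 9 subjects, 2 areas × 2 conditions × 6
depths — sizes chosen to make the full suite run in a couple of minutes on
one core while keeping Monte-Carlo error small relative to the asserted
bounds.

## Known limitations

The draining weights are a one-parameter family unless a full matrix is
supplied; the equi-volume geometry is per-column parametric rather than
mesh-based; the pipeline's QC hit-rate gate requires behavioural responses
that the simulator does not generate (the gate is implemented and tested on
constructed inputs); and the mixed-model layer treats the fitted `nlme`
machinery as the inferential authority rather than re-deriving degrees of
freedom for small samples.
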