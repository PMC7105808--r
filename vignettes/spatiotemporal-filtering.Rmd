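---
title: "Spatio-temporal filtering of independent components: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal filtering of independent components: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stfica)
```

## What this package computes

`stfica` implements an individual-subject analysis of task fMRI from a
three-condition tongue-movement block design, together with a synthetic-data
generator that plants known signal structure so that every stage can be
verified without scanner data. Two complementary branches operate on the same
pre-processed series:

* a **model-based branch**: a prewhitened voxel-wise general linear model with
  gamma-HRF regressors, contrasts of parameter estimates, and
  Gaussian-random-field cluster inference with local-maxima tables;
* a **model-free branch**: single-subject probabilistic spatial ICA into
  `K = 20` components, followed by *spatio-temporal filtering* — classifying
  components by the Pearson correlation of their time course with the expected
  hemodynamic response (temporal filter, `|r| > 0.4`, `p < 0.05`) and by the
  correlation of their spatial map with a library of ten canonical network
  templates (spatial filter, `r > 0.4`).

The temporal filter isolates brain activity time-locked to the task (in this
paradigm, a bilateral sensorimotor component); the spatial filter identifies
structured activity that is *not* time-locked — canonical networks such as the
default mode network — on a per-individual basis.

## The experimental design and its regressors

The paradigm presents movement blocks of 15 s in pseudorandomized order
(8 blocks for each of three conditions; no condition more than twice in a
row), with a 15 s rest after every third block and 3 s gaps otherwise, after
a 15 s fixation lead-in. The full timeline spans 543 s; at a repetition time
of 1.8 s, 308 volumes are recorded and the first four are discarded, leaving
304 for analysis.

The hemodynamic response is a gamma density parameterized by its mean lag
(6 s) and standard deviation (3 s), giving shape $k=(\mathrm{lag}/\mathrm{sd})^2=4$
and scale $\theta=\mathrm{sd}^2/\mathrm{lag}=1.5$ s, with mode $(k-1)\theta = 4.5$ s.
The kernel is normalized to unit sum, so convolving a unit boxcar yields a
unit plateau. Condition boxcars are convolved at 0.05 s resolution and
sampled at the volume times; each regressor is paired with its discrete
temporal derivative, a regressor of no interest absorbing small onset-timing
errors. The **expected response** — the reference series of the temporal
filter — is the union of all movement blocks convolved with the same kernel.
Slice-timing is deliberately ignored throughout.

A fixation lead-in of 15 s before the first block is an assumption of the
generator; its exact length is immaterial to all downstream estimates because
onsets are expressed relative to the first retained volume.

## Pre-processing

1. **Volume discard** (first 4 recorded volumes) with onset bookkeeping.
2. **Realignment** to the middle volume. The estimator is translation-only by
   design — the generator injects only translations — implemented as an
   adaptive integer-voxel search followed by two passes of per-axis parabolic
   refinement, and separable linear-interpolation resampling. Rotations are
   carried as zeros so that the displacement formulas stay general.
3. **Displacement metrics and exclusion.** Per-volume displacement combines
   translations with rotational arc on an 80 mm sphere in quadrature.
   Subjects are excluded when the mean relative (volume-to-volume)
   displacement reaches 1 mm or the mean absolute (volume-to-reference)
   displacement reaches 3 mm. Displacements are computed after the volume
   discard.
4. **Brain masking** by thresholding the temporal-mean image at 25 % of its
   robust (98th percentile) maximum, keeping the largest 6-connected
   component and filling interior holes. This is adequate for the synthetic
   heads the generator produces; it is *not* a substitute for surface-based
   brain extraction on real data.
5. **Smoothing and grand-mean scaling**: per-volume Gaussian smoothing at
   5 mm FWHM, then one global multiplicative factor setting the in-mask
   grand mean to 10 000 (a conventional target; only the single-factor rule
   matters).
6. **ICA-based denoising** (below), *then* high-pass filtering — the
   documented stage order places temporal filtering after denoising.
7. **High-pass filter**: at each time point a straight line is fitted by
   weighted least squares with Gaussian weights (SD `sigma = 45` s) centred
   there, and its value is subtracted; the global mean is re-added. The
   filter is linear, passes a 15 s-period oscillation at better than 0.9
   amplitude ratio and suppresses a 450 s drift below 0.2.

## Probabilistic spatial ICA

The in-mask data matrix (time x voxels) is demeaned voxel-wise; the global
spatial-mean time course is also removed so that the whitened spatial rows
are exactly zero-mean, which the fixed-point update assumes. PCA whitening
to `K` dimensions is followed by symmetric fixed-point ICA with the tanh
contrast (tolerance 1e-6, at most 500 iterations, up to 5 restarts).

One numerical choice deserves emphasis. With fixed `K = 20` the retained
subspace generally contains directions with no non-Gaussian contrast (pure
noise). For a Gaussian direction the expected tanh update vanishes (Stein's
identity), leaving a sampling-noise-driven wander with *no fixed point*, and
the symmetric decorrelation couples that wander into every other row — the
plain iteration therefore cannot meet any tight tolerance. We use a
**stabilized** iteration: full fixed-point steps for the first half of the
budget, then geometrically damped steps (factor 0.93 per iteration), with
update rows sign-aligned before blending (fixed points are defined only up
to sign; blending an unaligned row would cancel and re-randomize it).
Damping preserves the fixed points of the plain iteration — directions with
genuine contrast converge during the full-step phase — and freezes the
contrast-free directions at a deterministic, seed-reproducible rotation.

Components are returned with unit-variance time courses, maps scaled to
z-like units by the global residual standard deviation, signs fixed so every
map has positive skewness, and ordered by explained variance. Maps can be
thresholded by a two-class Gaussian mixture fitted by EM (deterministic
quantile-based initialization, 200 iterations, tolerance 1e-6): voxels whose
posterior probability of the higher-mean class exceeds 0.5 form the active
set; degenerate fits (a vanishing class weight, unseparated means, or a map
whose spread is at numerical-noise scale) yield an empty active set.
Negative activations are handled by thresholding the negated map where a
caller needs them.

## ICA-based motion denoising

Four features are computed per component: high-frequency content (the
frequency at which the cumulative periodogram reaches half the total power,
over Nyquist); the maximum absolute correlation with an expanded
realignment-parameter set (the six parameters, their first differences, and
one-volume shifts of each — a deliberate reduction of the full 72-regressor
expansion); the fraction of absolute map weight on brain-edge voxels; and
the fraction in CSF. A component is classified as noise when the CSF
fraction exceeds 0.10, the high-frequency content exceeds 0.35, or the point
(RP correlation, edge fraction) falls above the published linear decision
boundary; all three rules are configurable.

The edge band uses a **two-voxel** interior rim plus a one-voxel exterior
shell. With 5 mm FWHM smoothing on 3 mm voxels, a boundary-locked
component's weight spreads about two voxels inward; a one-voxel rim
systematically undercounts its edge fraction and misses genuinely
boundary-locked motion components.

Flagged components are removed by **non-aggressive (partial) regression**:
every voxel's series is regressed on *all* component time courses jointly,
and only the fitted contribution of the flagged components is subtracted, so
variance shared with retained components is untouched.

## The GLM branch

Ordinary least squares is followed by AR(1) prewhitening: the lag-1
autocorrelation of the residuals is estimated per voxel, smoothed spatially
(5 voxel FWHM), discretized to a 0.005 grid (far below the estimation noise
of the coefficient itself) so voxels sharing a coefficient are refit in one
batch. On AR(1) noise with coefficient 0.3 this brings the empirical
`|z| > 1.96` rate into the nominal band, where the unwhitened fit is
markedly anticonservative — the reason prewhitening exists.

Group maps use a method-of-moments one-sample mixed-effects estimator:
between-subject variance clamped at zero, inverse-variance weights, and a
t-to-z probability transform at `n - 1` degrees of freedom. This is a
documented simplification of two-stage Bayesian mixed-effects estimation;
at desk scale the difference is immaterial for calibration.

Cluster inference assumes a Gaussian random field: smoothness is estimated
from the spatial derivatives of the normalized residuals (the residuals of
the map being thresholded), clusters are 26-connected components above
`Z > 3.1`, and corrected p-values use the expected-Euler-characteristic
cluster count with the extent survival function
$\exp(-\beta k^{2/3})$; clusters with `p < 0.01` survive. The
discrete-difference derivative underestimates the true gradient for smooth
fields, biasing the FWHM estimate upward — a known approximation shared by
simple implementations; it affects absolute calibration of cluster p-values,
not the relative ordering, and the planted-signal checks pass with margin.
Local maxima are voxels not exceeded by any 26-neighbour, accepted in
descending z with lexicographic tie-breaks, suppressing neighbours within
20 mm, at most 100 peaks, each annotated from the toy label volume.

## The spatio-temporal filter

The temporal filter computes Pearson correlations between each component
time course and the expected response, with two-sided p-values from the t
transform at `T - 2` degrees of freedom (temporal autocorrelation is ignored
here, a documented caveat of the significance labels). Components with
`r > 0.4, p < 0.05` are flagged positive; `r < -0.4, p < 0.05` negative.

The spatial filter cross-correlates unthresholded z-scaled maps with each of
the ten template networks at zero spatial lag (a configuration switch
correlates mixture-thresholded maps instead; the unthresholded default is
the cleaner-behaved of the two ambiguity resolutions). All pairs with
`r > 0.4` are reported; a template is *present* for a subject when any
component exceeds the threshold, a component may match several templates,
and temporally flagged components are not excluded from spatial matching —
the report records both statuses side by side. Cohort summaries count, for
every template, the subjects with presence, listing all ten templates even
at count zero.

## The synthetic-data generator

The generator is first-class, tested code. It emulates:

* the acquisition (TR 1.8 s, 308 recorded volumes, 24 x 24 x 14 grid of
  3 mm voxels, 4-volume discard);
* a **task-locked bilateral sensorimotor plant** whose time course is
  constructed to hit an exact target correlation (default 0.7) with the
  expected response over the retained volumes, by mixing the expected
  response with band-limited noise orthogonalized against it;
* optionally an **anti-correlated occipital-like plant** (e.g. target
  -0.6), placed clearly interior to the head — a boundary-adjacent placement
  would be corrupted by the simulator's own motion edge artifacts rather
  than by anything the filter does;
* **network plants**: a template map combined with a sparse perturbation
  (extra blobs at individual-specific sites away from all template and plant
  centres, plus mild smooth noise) calibrated to an exact in-mask
  correlation (default 0.6) with its template. The sparse perturbation
  mirrors how an individual's network differs from a canonical map — by
  displaced or additional regions, not diffuse haze — and keeps the map
  super-Gaussian, which is what spatial ICA assumes of real components;
* an **edge-ring motion component** (one-voxel rim at the head boundary)
  whose time course follows the signed volume-to-volume translation change,
  and a **central CSF component** with a high-frequency (0.15 Hz-Nyquist)
  time course;
* **AR(1) voxel noise** (coefficient 0.3, innovation SD 1) and injected
  rigid translations (piecewise-constant drift with a brief 1 mm spike by
  default; an incessant ~1.2 mm jitter schedule for exclusion tests).

The ten-template library consists of sums of Gaussian blobs (SD 1.3 voxels
on the default grid) at fixed anatomically-inspired layout positions with a
small seeded jitter, constrained to pairwise in-mask correlation below 0.3;
construction fails on grids too small to separate them. Canonical network
maps are *not* bundled; `import_template_library()` accepts user-supplied
NIfTI maps in their place.

What the generator does **not** emulate: anatomy, physiological
(cardiac/respiratory) noise, slice-timing, susceptibility artifacts, and
rotational motion. Passing tests therefore demonstrate the pipeline's
correctness under its stated statistical assumptions, not robustness to
everything real scanners produce. The band-limited (0.01-0.1 Hz) network
time courses are an assumption; nothing in the analysis depends on their
exact spectrum.

Where the defaults come from: block timing, volume counts, TR, HRF
parameters, thresholds, `K = 20`, and exclusion limits are the study
conditions stated above; amplitudes (task 3, network 3, motion 2.5, CSF 2,
against unit-SD noise) and the motion schedules are the generator's own
choices of a realistic contrast-to-noise regime, fixed once. The recorded
volume count defaults to 308 so that the discard rule retains 304.

## Problem sizes used in the checks

The automated checks run at desk scale on one CPU: ten full-pipeline
subjects at the default protocol for the end-to-end filter and denoising
properties (plus ten no-plant subjects for specificity), three to five
planted sources across ten seeds for ICA recovery, a 16 x 16 x 8 grid of
AR(1) noise for GLM calibration, and fifty random binary maps for the
cluster-labelling oracle. These sizes were chosen so the complete suite
documents every claim while remaining comfortably reproducible on a laptop.

## Known limitations

* Translation-only realignment and intensity-threshold masking are
  fixture-grade; real data need full rigid-body registration and proper
  brain extraction.
* Cluster p-values inherit the discrete-gradient smoothness bias discussed
  above and the usual GRF approximations at modest smoothness.
* The temporal filter's p-values ignore temporal autocorrelation.
* Model order is fixed (`K = 20` for the filter branch; the denoising ICA
  uses `min(20, T/4)`); no Bayesian dimensionality estimation is attempted.
* The mixture-threshold EM fits two classes; strong negative activations
  are only handled by thresholding the negated map.
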