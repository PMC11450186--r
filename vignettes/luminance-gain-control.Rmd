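---
title: "Models and methods: rapid luminance gain control in the fly visual system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: rapid luminance gain control in the fly visual system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumigain)
```

## The problem

Contrast is the behaviorally relevant visual variable, but it is defined
relative to background luminance, which changes within hundreds of
milliseconds whenever gaze crosses a shadow boundary. Fly lamina monopolar
cells (LMCs; L2, L3) do not compute contrast stably across such changes:
their responses to a fixed-contrast grating grow with mean luminance. The
downstream transmedullary neurons Tm1 and Tm9 do: Tm1 is
luminance-invariant and Tm9 even amplifies responses at low luminance. This
package implements the computational machinery used to study how that
gain control arises: stimulus generation, an effective LMC model, a
natural-scene analysis of spatial pooling, a shunting-inhibition
normalization circuit, and the calcium-imaging analysis pipeline, all
exercisable on synthetic data.

## Units

Movies generated by the stimuli module are in normalized luminance
`L / I_max` in `[0, 1]`, with the physical maximum (`I_max`, default 21.7 in
units of 1e4 photons s^-1 photoreceptor^-1) carried as metadata. The model
stages, however, work in those physical units (so the five standard grating
means are 1.2, 2.6, 5.3, 7.9 and 10.6): the published membrane parameters
(`g_inv = 0.05`, `v_L = 0.3`, `alpha = 4`) only produce a sensible operating
range when `g_inv * s` is comparable to the leak voltage, which requires
luminances of order 1-10 on that scale. In fully normalized units the drive
`g_inv * s <= 0.05` would be negligible against `v_L = 0.3`, the response
would be nearly luminance-blind, and divisive normalization could not
produce gain control at all. `generate_recording()` converts movie
luminance with `i_max` where its gain laws need physical units.

## Stimuli

`make_drifting_grating()`, `make_off_edge()` and `make_ternary_noise()`
render the three standard protocols on a configurable screen (default
60 x 60 degrees, 0.5 degrees/pixel, 100 Hz; x is azimuth, y elevation,
origin at the screen center). Numerical choices:

* The grating's spatial phase is aligned so that a pixel center sits on the
  sine peak at epoch onset. Sampling a sinusoid on a pixel grid otherwise
  never attains the analytic extrema, and the rendered Michelson contrast
  would be biased low by up to `(pi / n)^2 / 2` at `n` pixels per
  wavelength. With the aligned phase the extrema are reached exactly over
  an epoch (and in every frame when the frame rate and pixel pitch are
  commensurate with the drift), so a nominal 100% contrast grating also
  measures 100%.
* Noise movies are generated at the 20 Hz update rate with one pixel per
  element (2.5-degree squares or 5-degree stripes), preceded by a 4 s
  full-field prelude at the intermediate level that later serves as the
  dF/F baseline. Element counts snap to whole pixels, with a warning when
  snapping changes the size by more than 5%.
* Apertures (disc, disc-with-annulus) clip at their boundary; the screen
  outside shows the epoch's mean luminance.

## The effective LMC model

The membrane potential obeys `dv/dt = -(v - v_L) + g_inv * s(t)`; because
neuronal integration is fast relative to the stimuli, the pseudo-stationary
solution `v = v_L + g_inv * s` is used throughout (an explicit-Euler mode
exists for validating that assumption, default off). The calcium read-out
is the rectified square `alpha * max(v, 0)^2`.

**Identifiability.** The read-out is exactly invariant under
`(alpha, v_L, g_inv) -> (alpha k^2, v_L / k, g_inv / k)`; no stimulus can
distinguish members of this family, so only two parameter combinations are
estimable. `fit_membrane_params()` therefore fixes the leak voltage as a
gauge (default `v_L = 0.3`, the published value) and estimates `g_inv` and
`alpha`; `alpha` enters the F1 amplitude linearly and is profiled out
analytically, leaving a one-dimensional bounded search over `g_inv` with
seeded random multi-starts. The full three-parameter least squares is
available (`v_L = NULL`) but warns that its solution is a ridge. L2
parameters are not published separately; the L3 values are used for both
cell types by default and are overridable.

## Natural scenes and the pooling-size loss

`synthesize_scene_ensemble()` emulates calibrated photographs of one scene
under several illuminations:

* **Reflectance**: an isotropic `1/f` (spectral exponent `beta = 1`)
  log-Gaussian field with log-sd 0.5, exponentiated to positivity — spatial
  correlations decay with distance as in natural images, and the
  reflectance range (roughly 30:1 over +/-3 sd) matches natural surfaces.
* **Illumination**: a smooth (8-degree correlation scale) log-normal
  component, partially shared between conditions, plus direct-sun patches
  obtained by soft-thresholding a smooth field — high-contrast lit regions
  with sharp shadow boundaries (lit/shadow gain 4 in sunny conditions and a
  muted 1.5 in the overcast rendering of the same shadow geometry).
* **Conditions**: the default four conditions cross two global levels
  (means 2 and 8, an exact 4x ratio enforced by rescaling) with two shadow
  geometries.

The generator does **not** emulate oriented structure, occlusion edges,
the sky/ground anisotropy, or photon noise; tests passing on these
ensembles demonstrate the pipeline's behavior under realistic second-order
statistics and illumination changes, not performance on any particular
photographed scene.

Gaze is modeled by `simulate_trajectory()`:
`T(z) = 30 sin(2 pi * 3 * omega_z * z) + gamma z + 60 N(0, 1)` with
`omega_z` the inverse horizontal scene length and `gamma = 1/3`. All
constants are in pixels as printed; the noise is i.i.d. per sample (the
alternative — one offset per trajectory — is not what the equation states),
sampling is at pixel resolution along z, and off-image points clip to the
nearest valid row.

**The loss.** For a condition pair (brighter = "sunny", dimmer = "shaded"),
`pooling_loss()` combines two order-1 Wasserstein distances in quadrature:
term 1 between the two conditions' normalized-response distributions
(stability across illumination), term 2 between the dimmer condition's
mean-centered raw and mean-centered normalized distributions (structure
retained after normalization). Conventions:

* Distances are computed from the raw samples (exact empirical-CDF
  integral), never from the kernel density estimate; the KDE (Scott's-rule
  bandwidth, 512-point grid spanning the samples +/- 3 bandwidths) is for
  reporting only. This removes bandwidth sensitivity from the loss.
* Term 2 rescales the normalized sample to the raw sample's mean before
  centering (`rescale_term2 = TRUE`). The two samples otherwise live on
  different scales (one was divided by a pooled background), and a purely
  scaling — hence shape-preserving — normalization should cost nothing. A
  normalization that collapses the distribution to a point costs the raw
  sample's mean absolute deviation, the correct limiting penalty.
* The printed equation indexes term 2 by the shade condition while the
  accompanying text says sun; the equation's reading is the default and
  `term2_condition = "sunny"` selects the other.

**What is pooled.** `scan_pooling_sizes()` normalizes the response image by
its disc-pooled *response* (uniform weights over pixels whose centers fall
in the disc, boundary-renormalized, leak `g_l = 0.05`). Pooling the
response rather than the raw scene luminance mirrors the normalization
circuit, whose wide-field unit sums lamina-neuron responses over columns —
and those lamina neurons are themselves luminance sensors. This choice
matters: dividing the rectified-quadratic response by pooled *luminance*
can never collapse the distribution at small pooling (the ratio retains
structure at every diameter) and the loss degenerates to a monotone
function of diameter; dividing by the pooled *response* reproduces the full
trade-off — tiny pooling drives `R / R_pool -> 1` and destroys structure,
global pooling leaves the between-condition shape mismatch — with a loss
minimum at intermediate diameters and, as in the recordings, a much larger
loss variance at sub-degree pooling. `pool = "scene"` retains the literal
scene-luminance reading.

Condition substreams for trajectories are keyed by condition label, so a
duplicated condition is sampled along identical trajectories and its pair
contributes exactly zero condition-mismatch (term 1).

## The normalization circuit

`tm_response()` implements `R = I / (g_l + J^p)` in the pseudo-stationary
regime, with `I` the center column's lamina input (L2 for Tm1, L3 for Tm9)
and `J = sum_i I_i` the wide-field pool (a sum, as printed, not a mean).
Columns are laid out as a 1-D row at the 5-degree column pitch spanning the
pooling diameter — 15 degrees gives three columns, matching the wide-field
neuron Dm12's three-column span; a trace's random phase is shared across
columns with per-column spatial offsets from the grating wavelength.
`p = 1` (linear, Tm1) yields luminance invariance; `p = 2` (quadratic, Tm9)
inverts the luminance dependence. The quadratic acts on the summed pool
(`J^2`, as printed), not on summed squares.

The leak conductance is not published. The default `g_l = 0.332` is the
output of `calibrate_leak_conductance()`: the value minimizing the
magnitude of the linear model's F1-versus-log-luminance slope at 15-degree
pooling (golden-section search on `log g_l`, seeded fixed phases). Because
the F1 amplitude is averaged over 1000 uniformly random phases and the
per-trace F1 is almost phase-independent, simulated slopes are stable to
several decimals across seeds.

## Imaging analysis

* **dF/F**: baseline is the trace mean by default, or the mean of the
  first 4 s (the noise prelude) for reverse correlation.
* **Reliability**: mean of *pairwise* Pearson correlations across trials
  (not trial-versus-mean), keep at >= 0.6; zero-variance trials make the
  value undefined and flag the ROI.
* **F1 amplitude**: `2 |DFT coefficient| / N` over a whole number of
  stimulus periods, nearest-bin lookup within half a bin; a pure sinusoid
  of amplitude A returns A.
* **STRF**: trace linearly interpolated to the 20 Hz update rate, prelude
  dF/F, mean-centered; stimulus levels mapped to -1/0/+1; kernel
  `1/(T - tau) * sum_t r_t s(t - tau)` over a 2 s backward window.
  Acceptance thresholds: peak |amplitude| >= 0.005 (default) or >= 0.003
  with SNR >= 10 (low-SNR mode). The literal SNR ("peak over mean") divides
  by a near-zero mean for sign-balanced kernels, so the package uses peak
  absolute over *mean absolute* value by default and exposes the literal
  definition behind a flag.
* **Filters**: temporal filter at the spatial argmin, spatial filter at
  the temporal argmin (OFF cells have negative kernels); argmin ties break
  to the first occurrence scanning space within each lag. The FWHM uses the
  exact `2 sqrt(2 ln 2)` (2.3548, printed rounded as 2.355). Gaussian fits
  are bounded quasi-Newton with moment-based initialization; failures are
  flagged on the result, never raised.
* **Heatmaps**: order-1 (bilinear) zoom with endpoint alignment — linear
  ramps interpolate exactly — from 5x5 to 25x25, then Gaussian smoothing
  with sigma 10 interpreted in zoomed-grid pixels (the source does not give
  the units; configurable), then 8 evenly spaced contour levels (linear,
  not quantile, spacing assumed).

## Synthetic recordings

`generate_recording()` builds GCaMP-like traces from linear-nonlinear
neurons: Gaussian spatial weighting of the movie, polarity-signed contrast
drive, one of three gain laws (multiplicative luminance scaling; division
by the epoch-mean pooled luminance; division by its square), convolution
with a biexponential indicator kernel (50 ms rise, 400 ms decay; `"delta"`
for instantaneous), resampling to the 10-15 Hz imaging rate, and i.i.d.
Gaussian noise per trial scaled to a fraction of the response sd. Indicator
saturation, neuropil contamination, bleaching and motion are deliberately
not modeled — the generator exists to validate estimators against known
ground truth, not to imitate raw data.

## Connectome geometry

`projection_plane()` takes the leading principal component of a neuron's
presynaptic-site coordinates as its transmedullary axis (signs
canonicalized against +z, then +y, +x, for reproducibility);
`hull_metrics()` projects a partner's synapse cloud onto the perpendicular
plane and reports the convex-hull area, the maximal pairwise projected
extent (all points; hull vertices give the same value), and that extent
divided by the 11.2 um medulla column pitch. Neuron volumes are
represented by their synapse point clouds; projecting points onto the
plane realizes the "flatten the volume into a single plane" measurement
without EM meshes.

## Problem sizes and reproducibility

Default analysis sizes: 256 x 256 px scenes at 0.25 degrees/pixel with 15
trajectories per condition and 8 pooling diameters (0.5-64 degrees); 1000
random-phase traces per luminance for circuit curves; 10 minutes of
ternary noise for receptive-field recovery. These match the study
protocols while keeping a full run to seconds on one core. Every
stochastic stage takes a seed and derives per-stage substreams;
`run_pipeline()` writes a manifest with seeds and MD5 hashes, and repeated
runs of one configuration are bit-identical.

## Known limitations

* The pseudo-stationary membrane ignores indicator and membrane dynamics;
  temporal filtering enters only through the synthetic-recording kernel.
* The scale degeneracy of the membrane model means fitted `(g_inv, v_L,
  alpha)` are meaningful only within the stated gauge.
* The pooling scan's absolute loss values depend on the synthetic
  ensemble's dynamic range; only the shape of the loss-versus-diameter
  curve (and the variance ordering) is interpretable.
* The circuit model is one-dimensional in space and omits Tm dendritic
  conductances, receptor kinetics and direction selectivity.
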