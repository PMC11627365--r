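---
title: "Methods: from fluorescence images to dosage-phenotype maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from fluorescence images to dosage-phenotype maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`parmap` quantifies PAR polarity and asymmetric-division phenotypes in
single *C. elegans* zygote images and relates them to protein dosage across
RNAi-rundown cohorts. This vignette is the package's account of the models
it fits, the parameters that matter, the numerical choices behind them, and
what validation on synthetic embryos does and does not establish.

## The measurement model

### Fluorescence correction

Autofluorescence excited at 488 nm has a much broader emission spectrum
than GFP, so its contribution to the green channel can be estimated from a
parallel red-shifted channel. `fit_af_model()` fits the linear model
`signal = m * AF + b` on GFP-negative control embryos and
`correct_image()` subtracts the inferred autofluorescence. Two regression
modes exist because they fail differently:

* **pixel mode** pools in-mask pixels (deterministically subsampled to at
  most 1e5 by a fixed stride). With per-pixel noise on the AF channel it is
  an errors-in-variables regression, and the slope attenuates by
  `var(AF_true) / (var(AF_true) + var(noise))`; it is the right choice when
  spatial AF structure is strong relative to noise.
* **embryo mode** regresses per-embryo in-mask means, where AF noise
  averages out; it needs AF variation *between* embryos, which unlabeled
  cohorts provide naturally. This is the mode used for slope calibration in
  the package's own validation.

Corrected intensities may be negative and are never clipped — clipping
would bias whole-embryo means toward zero signal. Channels imaged in
configurations with negligible autofluorescence (mNG, mCherry) instead use
`subtract_flat_background()`, a scalar measured on unlabeled embryos.
Local-background image subtraction is not applied by default; it can
usually be omitted, and the AF intercept absorbs a flat camera baseline.

### Segmentation and straightening

`segment_embryo()` thresholds a Gaussian-blurred copy (sigma 2 px, Otsu),
fills holes, keeps the largest object (minimum 2,000 px^2), and fits a
truncated Fourier series (8 harmonics) to the ordered boundary pixels. The
Fourier contour is then *refined*: each point is moved along its local
normal to the cross-membrane intensity peak (parabolic subpixel
refinement), and finally the whole contour is recentred using the fitted
Gauss + erf centre of the mean profile. The refinement matters because a
threshold boundary sits wherever the blurred edge crosses the Otsu level —
several pixels outside the membrane — whereas all downstream quantities
are defined relative to the membrane ridge. The refinement assumes a ridge
exists; for ridge-free images (autofluorescence controls) use
`refine = "none"`. When several complementary markers are available,
segmenting on their sum is recommended: the total membrane signal of
complementary PAR proteins is approximately uniform around the cortex.

The contour is resampled uniformly in arc length (default 1,000 points),
anchored with `s = 0` at the anterior pole and oriented counterclockwise.
Anterior is assigned by comparing the mean of a marker channel in the 20%
arcs adjacent to the two long-axis poles (`anterior_marker = FALSE` for
posterior markers); for unlabeled inputs the caller states the orientation
(`anterior = "left"`).

`straighten_cortex()` samples the image along inward normals over a
50-pixel window (12.8 um at the default 0.256 um/px — the pixel scale is
back-computed from that equivalence) and applies a circular 20-pixel
(5.1 um) rolling average along the perimeter; circular because the cortex
is closed, which also conserves the perimeter mean of every column
exactly. Interpolation is bilinear by default with a bicubic (Catmull-Rom)
option: bilinear adds ~1/6 px^2 of variance to the point-spread, which
attenuates a 0.5 um ridge amplitude by about 2%; bicubic keeps the
attenuation below ~0.5% and is what the tightest round-trip validations
use.

### Membrane/cytoplasm decomposition

Each cross-membrane profile is modelled as
`A G(x; c, w_g) + (C/2)(1 + erf((x - c)/(w_e sqrt(2)))) + O`: a Gaussian
membrane ridge (amplitude `A`, the membrane concentration) over an
error-function cytoplasmic step (plateau `C`). Numerical design:

* **Width sharing.** `w_g`, `w_e` and `O` are fitted once on the
  position-averaged profile by a bounded Levenberg-Marquardt fit
  (`minpack.lm::nlsLM`; `c` within ±2 um, widths in [0.2, 2] um, ftol
  1e-8, 200 iterations, started from both a ridge-peak and a step-midpoint
  centre guess) and then held fixed per position. Fully free per-position
  four-parameter fits are unstable at low signal.
* **Per-position solve.** With widths fixed, the model is linear in
  `(A, C)` at a given centre, so each position is solved by a grid search
  over `c` (0.1 um steps) with closed-form nonnegative least squares,
  followed by six rounds of grid halving (final resolution ~0.003 um).
  Parabolic interpolation of the residual is deliberately avoided: when
  `A << C` the residual profile in `c` is strongly asymmetric and the
  parabolic vertex is biased, which leaks step signal into `A`.
* **Degeneracy guard.** The Gaussian component is exactly the derivative
  of the erf step with respect to its centre, so for profiles with no
  ridge the full model is first-order unidentified in `(A, c)`. The global
  fit therefore also fits the nested erf-only model and keeps the ridge
  terms only if they reduce the residual significantly (F test, p < 1e-3).
  If the erf-only model wins, `A = 0` globally and the per-position centre
  is held at the shared value rather than searched — a free centre would
  only absorb noise into `A`. This keeps step-only profiles at the noise
  floor instead of acquiring a systematic positive amplitude.
* **Failure isolation.** Non-finite per-position solutions are flagged and
  excluded; more than 20% flagged positions is a hard error.

Cortical levels are means of `A(s)` over pole-centred arcs of 33% of the
perimeter (anterior for aPARs, posterior for pPARs). Total dosage is the
in-mask mean intensity (mask eroded 1 px, standing in for a manually drawn
whole-cross-section ROI) divided by the control-cohort mean.

## Polarity metrics

The composite asymmetry index
`((A_A - A_P) - (P_A - P_P)) / (A_A + A_P + P_A + P_P)` takes aPAR and pPAR
concentrations at the two poles, each normalized to wild-type peak levels.
Two points are genuinely open in the source methods and were decided as
follows: the pole concentrations are the 33% pole-arc cortical means
(consistent with the cortical-level definition, rather than semicircles),
and the wild-type peak is the control-cohort mean of each protein's
per-embryo maximum of `A(s)`. Since the index is scale-invariant, any
common normalization convention cancels; only the aPAR:pPAR normalization
*ratio* matters, and using the same convention for both proteins keeps it
near 1.

Single-protein indices use semicircle or pole-arc means with the sign
arranged so correctly polarized embryos are positive: `(A-P)/(A+P)` for
anterior-enriched proteins (MEX-5), `(P-A)/(A+P)` for posterior-enriched
(PAR-1). The PAR-1 gradient magnitude is reported unnormalized (`P - A`,
intensity units) from ROIs containing both membrane and cytoplasm, because
the relative contribution of the two pools is unknown.

Domain boundaries are half-max crossings of `A(s)`, scanned outward from
the stated pole with linear interpolation; profiles that never cross
half-max return a flagged missing value, and more than one crossing per
side is flagged (`multiple_crossings`). `detect_domains()` is a
threshold classifier standing in for by-eye scoring: arcs with
membrane:cytoplasm ratio above `theta_high = 1.5` (merged across the
`s = 0` wrap, minimum arc 5% of the perimeter) are counted; traces with no
arc are `no_domains` below `theta_low = 1.2` and `unclear` between the
thresholds. The thresholds are free parameters of the proxy, stated in the
configuration — they are not claimed from data. The ASI bands used only
for *labeling* bimodal regimes (retained > 0.9, reduced < 0.75) are
exposed as constants, not used for inference.

## Division and spindle metrics

Size asymmetry is AB area over whole-embryo area on midplane masks.
Asynchrony is `t_P1 - t_AB` in seconds (signed; negative values are
flagged as inverted). Oscillation magnitude is the *population* SD of the
off-axis displacement `y` between the annotated prometaphase and telophase
frames — the source does not state the normalization, and at the ~30+
frames of a typical window the sample/population difference is immaterial.
Severing velocities smooth `x` and `y` with a 10-frame moving average
(1 s at the assumed 10 fps of streamed acquisition), measure Euclidean
displacement over every rolling 1-s window (advanced one frame at a time,
window length `round(window_s / frame_interval)`), and report the maximum
per pole plus the posterior-minus-anterior difference. Event annotations
are inputs (CSV), mirroring manual staging; no mitotic-stage detection is
attempted.

## Dose-response statistics

`lowess_bootstrap()` is a local linear smoother with tricube weights over
the span-fraction nearest neighbours of each of 100 grid points, with 95%
percentile bands from case-resampling bootstrap (n = 1,000, seeded;
intervals are widened minimally where needed so the band always brackets
the point fit). A flat-kernel option exists purely as a verification hook
(span 1 + flat kernel reproduces ordinary least squares). The default span
is 0.5, but the span must be chosen below the width of the sharpest
feature to be resolved: a local-linear smoother has bias
`~ f''(x) sigma_K^2 / 2`, and for a Hill response with K = 0.5, n = 6
(transition width ~0.2 on a unit dosage axis) a span of 0.5 over uniform
dosages produces shoulder bias of order 0.07 — larger than the 0.05
tracking tolerance the validation demands — while a span of 0.3 resolves
the sigmoid comfortably. The package's Hill-tracking validation therefore
runs at span 0.3; robustness iterations are off by default.

`gaussian_window_stats()` slides a Gaussian weight of half-width `h = 0.1`
along the dosage axis and pairs the weighted mean dosage with the weighted
phenotypic variance `sum(w (y - ybar_w)^2) / sum(w)` (plain
sum-of-weights normalization, no effective-sample-size correction).
"Half-width" is interpreted as the Gaussian sigma; an FWHM reading is one
configuration flag away (`interpretation = "fwhm"`), as the source wording
does not fix it. Variance profiles of Hill-shaped responses with additive
noise peak where the curve is steepest relative to the window — near the
inflection, i.e. near 50% dosage for the default map. Window centres where
the total weight underflows return flagged missing values.

The compensation fraction `(x_het_null - x_het_wt) / (x_hom - x_het_wt)`
is 0 for no compensation and 1 for full; values outside [0, 1] are
permitted and flagged, and per-genotype SEMs propagate to a delta-method
95% CI.

## The synthetic-embryo generator

`render_embryo()` inverts the measurement model: an elliptical midplane
(default semi-axes 25 x 15 um, a typical zygote; 0.256 um/px) whose
intensity at each pixel is `A(s) G(d) + C Phi(-d/w)` with `d` the signed
distance to the ellipse (computed by per-pixel Newton projection onto the
boundary) and `s` the perimeter position of the nearest boundary point.
The membrane profile `A(s)` is two plateaus joined by a logistic in the
perimeter coordinate (sharpness default 20); the ridge SD is 0.5 um
(PSF-like). An autofluorescence channel (interior fill, linear A-P tilt)
bleeds into signal channels by a configurable factor; a camera offset and
additive Gaussian read noise complete the model (a Poisson shot-noise
option is deliberately absent so renders are exactly reproducible from the
seed). `polarized_embryo_spec()` solves the plateau blend analytically so
the *true* composite ASI — defined through the same 33% pole-arc means the
pipeline measures — equals a requested target; realizing targets up to
~0.95 inside 33% arcs requires a sharp boundary, so that helper defaults
to sharpness 60 (a near-wild-type boundary width of a few percent of the
perimeter).

`simulate_rundown_cohort()` draws uniform dosages, maps them through Hill
curves `p_min + (p_wt - p_min) d^n / (d^n + K^n)` (defaults: asynchrony
saturating at 120 s — the ~2-min wild-type AB-P1 delay — and AB fraction
at 0.57, both with K = 0.5, n = 6, inflection near 50% depletion), and
adds Gaussian measurement noise. The asymmetry index follows a bimodal
regime: above a dosage window [0.25, 0.75] every embryo retains
near-wild-type ASI; across the window the retention probability falls
linearly from 1 to 0; non-retaining embryos fall on a reduced branch
linear in dosage. The window and retention law reproduce the *qualitative*
structure of bimodal polarity loss, not fitted frequencies. Measurement
noise magnitudes (asynchrony 6 s, AB fraction 0.01, ASI 0.02) are free
parameters chosen as plausible assay noise; embryo-to-embryo variance at
fixed dosage is not calibrated to any dataset.

`simulate_spindle_track()` builds sinusoidal transverse oscillations
(posterior amplitude, anterior at 0.4x in antiphase) with constant per-pole
drift and annotated events; its analytic oscillation SD is
`amplitude / sqrt(2)`. `simulate_two_cell()` splits an elliptical mask at
the column order statistic so the AB area fraction is exact to one pixel,
and places furrow events the stated asynchrony apart.

What the generator does **not** emulate: 3-D structure and out-of-focus
light, photobleaching, cortical flows, nuclei and spindle texture in the
cytoplasm, pixel-correlated noise, or embryo-shape variability beyond the
ellipse. Passing the round-trip validations therefore demonstrates the
*correctness of the estimators under their own measurement model* — that
segmentation, straightening, decomposition and the downstream statistics
are unbiased and numerically stable at realistic noise — not robustness to
every artefact of real microscopy.

## Reproducibility and problem sizes

Every stochastic routine takes an explicit seed and restores the caller's
RNG state; identical configuration and seeds give byte-identical CSV
outputs (numeric columns are serialized at full precision, `%.17g`).
Images round-trip through 32-bit-float multi-page TIFF with a fixed affine
intensity map recorded in a JSON sidecar. The validation suite uses
problem sizes chosen to exercise the estimators well inside their
asymptotic regime while keeping a full run inside a couple of minutes on
one core: 100-profile rasters for parameter recovery, 20 rendered embryos
across four asymmetry levels for the image round trip, 100 traces for
domain classification, cohorts of 200 for the dose-response statistics,
and small multi-embryo pipelines (400 contour points) for determinism.

## Known limitations

* With shared widths and a fixed PSF-like ridge, amplitude estimates are
  attenuated by interpolation smoothing (about 2% under bilinear
  sampling); ratios and indices cancel this almost entirely.
* Near-zero membrane concentrations sit on an identifiability floor set by
  the Gauss/erf-derivative degeneracy; the F-test guard removes the
  global bias but per-position estimates at a ridge-free pole of an
  otherwise-ridged embryo retain a small positive noise floor.
* The domain classifier is a fixed-threshold proxy for human scoring and
  has no notion of "marginal enrichment" beyond its two thresholds.
* The pipeline quantifies single NEBD-stage snapshots; time-lapse
  tracking, flow measurement (PIV) and particle tracking are out of scope
  and their outputs are consumed as tables.
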