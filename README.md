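# parmap

Quantitative mapping of PAR protein dosage to polarity and
asymmetric-division phenotypes in *C. elegans* zygotes.

## The problem

The one-cell *C. elegans* embryo divides asymmetrically under the control of
the PAR polarity network: anterior proteins (PAR-3, PAR-6, PKC-3) and
posterior proteins (PAR-1, PAR-2) occupy mutually exclusive cortical domains
that set daughter-cell size and fate. Asking how robust this system is to
protein dosage requires, for each embryo, accurate fluorescence quantitation
(autofluorescence-corrected total and cortical concentrations), polarity
metrics (asymmetry indices, domain boundaries, domain counts), division
phenotypes (two-cell size asymmetry, AB–P1 cytokinesis asynchrony, spindle
dynamics), and dose–response statistics over RNAi-rundown cohorts. `parmap`
implements that pipeline for R, together with a synthetic-embryo generator
that produces ground-truth images, cohorts and spindle tracks so every stage
can be validated without microscopy data.

## Core models

**Cortical quantitation.** A subpixel embryo contour (Fourier fit to the
segmented boundary, refined onto the membrane ridge) is straightened into a
50-pixel-wide (12.8 µm) band following the membrane, smoothed by a 20-pixel
(5.1 µm) circular rolling average along the perimeter. Each cross-membrane
intensity profile is decomposed as

```
I(x) = A exp(-(x - c)^2 / (2 w_g^2)) + (C/2) (1 + erf((x - c) / (w_e sqrt(2)))) + O
```

a Gaussian membrane ridge of amplitude `A` (the membrane concentration) over
an error-function cytoplasmic step of plateau `C`. Widths and offset are
fitted once on the position-averaged profile and held fixed; `A(s) ≥ 0`,
`C(s) ≥ 0` and the centre `c(s)` are refitted at every perimeter position by
constrained least squares. Regional cortical levels are means of `A(s)` over
the anterior- or posterior-most 33% of the perimeter.

**Correction.** Spectral (SAIBR-style) autofluorescence correction fits
`signal = m · AF + b` on GFP-negative control embryos using a red-shifted AF
channel, then subtracts the inferred autofluorescence pixel-by-pixel or
embryo-by-embryo; mNG/mCh channels use flat background subtraction from
unlabeled embryos.

**Polarity metrics.** The composite asymmetry index combines aPAR and pPAR
pole concentrations (wild-type-peak normalized):

```
ASI = ((A_A - A_P) - (P_A - P_P)) / (A_A + A_P + P_A + P_P)
```

plus single-protein semicircle ASIs `(A-P)/(A+P)` (sign per protein),
gradient magnitudes `P - A`, half-max domain boundaries, membrane:cytoplasm
ratios, and a threshold-based monopolar/bipolar/no-domain classifier.

**Division phenotypes.** AB area fraction from two-cell masks, asynchrony
`Δt = t_P1 - t_AB` (≈2 min in wild type), spindle-pole oscillation magnitude
(population SD of off-axis displacement from late prometaphase to
telophase), final pole positions, and post-severing maximum pole velocities
(10-frame smoothing, rolling 1-s displacement windows).

**Dose–response.** Dosage normalization to control means, the compensation
fraction `(x_het_null - x_het_wt) / (x_hom - x_het_wt)`, LOWESS trends
(local linear, tricube, span-nearest-neighbours) with case-resampling
bootstrap bands, and Gaussian moving-window (half-width 0.1) weighted
phenotypic variance profiles, which peak near the inflection of Hill-type
dosage–phenotype maps.

## Worked example

Render a polarized two-protein embryo with known ground truth, quantify it,
and recover its asymmetry:

```r
library(parmap)

spec <- polarized_embryo_spec(target_asi = 0.6, M = 100, cytoplasm = 30,
                              noise_sd = 2, seed = 42)
emb <- render_embryo(spec)
emb$image
#> <embryo_image> 180 x 258 px (0.256 um/px), channels: apar, ppar, af

contour <- segment_embryo(emb$image, channel = c("apar", "ppar"),
                          anterior_channel = "apar")
contour
#> <boundary_contour> 1000 points, perimeter 127.55 um

prof_a <- fit_membrane_profiles(straighten_cortex(emb$image, contour, channel = "apar"))
prof_p <- fit_membrane_profiles(straighten_cortex(emb$image, contour, channel = "ppar"))
prof_a
#> <membrane_profile> 1000 positions (0 flagged)
#>   widths: w_gauss = 0.512 um, w_erf = 0.592 um, offset = -0.023
#>   A(s): median 61.06 [24.71, 98.77]

peak_a <- max(prof_a$positions$A); peak_p <- max(prof_p$positions$A)
asi_composite(cortical_mean(prof_a, "anterior")  / peak_a,
              cortical_mean(prof_a, "posterior") / peak_a,
              cortical_mean(prof_p, "anterior")  / peak_p,
              cortical_mean(prof_p, "posterior") / peak_p)
#> [1] 0.593   # ground truth 0.6

domain_boundary(prof_a, from_pole = "anterior")$boundary
#> [1] 0.248   # true boundary at 0.25 of the perimeter
```

The 25 µm × 15 µm embryo's analytic perimeter (Ramanujan) is 127.64 µm; the
measured contour is within 0.1%. The measured composite ASI of 0.593 is
within 0.01 of the generator's ground truth, and the aPAR domain boundary is
recovered at 0.248 of the perimeter against a true 0.25.

For whole directories of images, `pipeline_config()` + `run_pipeline()`
compose correction, segmentation, straightening, profile decomposition,
polarity metrics and dose–response outputs into one reproducible run that
writes `cohort.csv`, optional trend/variance profiles, and a manifest.

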