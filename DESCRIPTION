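Package: parmap
Title: Quantitative Mapping of PAR Protein Dosage to Polarity and
    Asymmetric Division Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-quantitation and dose-response toolkit for studying how
    PAR polarity protein dosage maps to polarity and asymmetric-division
    phenotypes in C. elegans zygotes.  Provides spectral autofluorescence
    (SAIBR-style) and flat background correction, embryo segmentation with
    subpixel Fourier contours, cortical linescan straightening, decomposition
    of cross-membrane intensity profiles into Gaussian membrane and
    error-function cytoplasm components, polarity asymmetry indices and
    domain calling, two-cell division and spindle-track metrics, LOWESS
    dose-response trends with bootstrap confidence bands, Gaussian-window
    weighted variance profiles, and a synthetic-embryo generator that
    renders ground-truth images, rundown cohorts and spindle tracks for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    tiff,
    jsonlite,
    yaml,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
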