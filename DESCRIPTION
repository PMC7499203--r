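Package: spinequant
Title: Ratiometric Quantification of Fluorescent Puncta in Dendritic Spines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Watershed-based calling of fixed-size (5-pixel) regions of
    interest on the phalloidin (F-actin) channel of two- or three-channel
    confocal images of dendritic spines, ratiometric corrected-intensity
    (green/red) measurement with mode-based background subtraction,
    per-animal normalization, bilateral (contralateral vs ipsilateral)
    top-N and histogram statistics, and a rank-based third-channel
    colocalization ratio. Includes a synthetic multi-channel image and
    cohort generator with ground truth for validating every stage of the
    pipeline, plus Monte-Carlo calibration utilities for power and type-I
    error of the paired lateralization test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
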