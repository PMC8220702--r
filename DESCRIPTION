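Package: lesionruler
Title: Semi-Automated Unidirectional Lesion Measurement by Scale-Space
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates the RECIST-style longest in-plane diameter of a lung
    lesion on a single CT slice from one user-supplied seed point.  A binary
    classifier decides whether the lesion framed in a 128x128 patch appears
    larger or smaller than 32 pixels; searching over a ladder of bicubic
    magnifications for the scale at which that decision flips, and combining
    the flip magnification with the DICOM pixel spacing, yields the physical
    diameter.  Ships a synthetic lesion-phantom generator with exact
    ground-truth diameters, a minimal single-frame DICOM reader/writer, an
    analytic oracle classifier and a small trainable convolutional reference
    classifier, and the full radiologist-agreement evaluation battery:
    ICC(2,1) with F-based confidence intervals, Bland-Altman percent-difference
    analysis with 95% limits of agreement, pixel-difference metrics, and
    Bonferroni-corrected pairwise group comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    grDevices,
    graphics,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    png
Config/testthat/edition: 3
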