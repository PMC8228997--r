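Package: corneaquant
Title: Semi-Automatic Vessel Segmentation and Density Quantification for
    Corneal Flat Mounts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies corneal lymphangiogenesis and hemangiogenesis from
    whole-mount RGB fluorescence images. Implements a semi-automatic
    segmentation chain (channel isolation, anisotropic diffusion, median
    filtering, morphological top-hat background subtraction, multiscale
    Frangi vesselness, region-restricted Otsu thresholding, small-object
    removal and optional manual correction masks), converts binary vessel
    masks to area densities relative to a user-drawn corneal region of
    interest, and provides the accompanying clinical scoring aggregations
    (systemic GVHD and blepharitis scores), comparative-threshold qPCR
    normalisation and nonparametric cohort statistics (Mann-Whitney U,
    Friedman with Bonferroni post hoc, Pearson correlation, Kolmogorov-
    Smirnov normality screening, Kaplan-Meier/log-rank). A synthetic
    flat-mount generator with known vessel ground truth and a synthetic
    cohort generator make the full pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    tiff,
    survival,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
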