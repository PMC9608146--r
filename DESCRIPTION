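Package: stainquant
Title: Quantification of Tri-Lineage Stem-Cell Differentiation from Stained Brightfield Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch pipeline for quantifying mesenchymal stem cell
    differentiation (adipogenic, chondrogenic, osteogenic) from two-dye
    brightfield histology images. Implements flat-field illumination
    correction from darkfield/brightfield calibration pairs, Beer-Lambert
    optical-density colour deconvolution with user-defined stain vectors,
    histogram auto-thresholding (Otsu and friends), per-image area fractions
    and the differentiation ratio (DR), donor-level normalized DR, pellet
    area measurement, and a univariate repeated-measures ANOVA over donor
    condition means. Ships a forward renderer for ground-truth synthetic
    studies and a command-line front end for batch runs.
License: MIT
Encoding: UTF-8
Imports:
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
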