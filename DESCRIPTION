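Package: dermquant
Title: Differential Expression, Gene-Set Permutation Testing, and
    Image and Assay Quantification for Dermatitis-Model Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for treated-versus-vehicle time-course studies
    of atopic-dermatitis mouse models. Provides a minimal negative-binomial
    differential-expression engine (median-of-ratios normalization,
    trend-shrunk method-of-moments dispersions, per-gene Wald tests,
    Benjamini-Hochberg adjustment), a gene-group permutation test on the
    median absolute log2 fold change with an exhaustive-enumeration oracle,
    hierarchical-clustering heatmap export of fold-change matrices,
    fluorescence-image quantification (maximum-intensity projection,
    intensity-window binarization, innervation area fraction,
    size-filtered cell counting), bead-calibrated absolute cell counts,
    four-parameter logistic ELISA standard-curve fitting and inversion,
    the accompanying behavioral statistics suite (t tests, one- and two-way
    ANOVA, Tukey-Kramer/Sidak/Holm-Sidak post hoc families, control-pooling
    rule), and synthetic-data generators with known ground truth for every
    stage, plus an end-to-end pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    minpack.lm,
    car,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
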