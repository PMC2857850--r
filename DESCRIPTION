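Package: gskernel
Title: Genomic Prediction with Ridge Regression and Geostatistical Kernel
    Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Genome-wide selection by mixed-model ridge regression and its
    geostatistical kernel extensions.  Biallelic markers are coded -1/0/1 and
    the genetic covariance between individuals is modelled either as the
    marker cross-product (ridge regression) or as a distance-decay correlation
    function (linear, quadratic, power, exponential, Gaussian or spherical) of
    the Euclidean distance between marker-code vectors.  Variance components
    are estimated by restricted maximum likelihood with the distance-decay
    range parameter profiled out, and breeding values of phenotyped and
    unphenotyped individuals are obtained by best linear unbiased prediction.
    Also provides a two-stage logistic growth-curve extrapolation that
    supplies known within-individual error variances, an extended
    variance-component model for father, mother and cross effects, model
    comparison by AIC and prediction accuracy, and a reproducible simulator of
    multi-family cross populations with repeated growth measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
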