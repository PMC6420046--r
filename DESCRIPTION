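Package: multibag
Title: Multiphase Nonrespondent-Subsampling Designs for Hunting Bag Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design-based estimation of total hunting bags under unit
    nonresponse, using repeated subsampling of nonrespondents: the
    Hansen-Hurwitz two-phase estimator, its generalization to any number of
    mailing waves (the El-Badry multiphase estimator), their theoretical
    sampling variances and a general unbiased sampling-variance estimator.
    Includes a hurdle-at-zero Poisson superpopulation generator for finite
    hunter populations, a null-harvest-driven nonignorable nonresponse
    mechanism, and a Monte Carlo engine computing bias indices of point and
    variance estimators over parameter grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    parallel,
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
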