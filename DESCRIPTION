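Package: echoagree
Title: Duplicate-Measurement Agreement and Discrimination Analysis for
    Automated Echocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical toolkit for evaluating an automated echocardiography
    reader against reference (core-laboratory) readers. Implements relative
    yield accounting, robust bias (median difference) and scaled percentile
    precision with percentile-bootstrap confidence intervals, Bland-Altman
    limits of agreement, root-mean-square error, reference change values,
    exact linear quantile regression for precision-range modelling,
    image-quality stratified tests (Kruskal-Wallis, Brown-Forsythe Levene),
    midrank AUC with DeLong paired comparison, age- and sex-matched
    case-control construction, and a synthetic cohort generator with known
    ground truth that reproduces the statistical structure of right-heart
    echocardiographic measurements in pulmonary hypertension.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    car,
    pROC,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
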