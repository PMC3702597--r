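Package: ssnr
Title: Training Sample Size Determination for Expression-Based
    Classifiers via the Scale of Signal-to-Noise Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding how many training samples are needed to
    build a reliable two-class outcome classifier from log-scale gene
    expression data.  The package scores genes by their signal-to-noise
    ratio (SNR), summarises an endpoint's intrinsic predictability by the
    scale of the SNR vector (SSNR, the range max - min over genes), and
    implements a two-stage protocol: evaluate SSNR on 60 training samples
    (threshold 2), then if necessary on 120 (threshold 1), to declare the
    sample size sufficient or the endpoint poorly predictable.  A
    repeated-subsampling learning-curve engine (Matthews correlation
    coefficient versus training size, with a marginal-value index per
    step), nearest-centroid/kNN/linear-SVM classifiers with
    cross-validated feature-count selection, positive and negative
    control endpoint constructors, and a calibrated synthetic two-class
    expression data generator are included so the whole workflow can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    e1071,
    graphics,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
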