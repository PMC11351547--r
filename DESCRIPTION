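Package: echocalc
Title: Aortic Valve Localization and Calcification Screening in Echocardiograms
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A fully automatic pipeline for screening aortic valve
    calcification in parasternal short-axis echocardiography frames.
    Provides ultrasound sector (cone) extraction and standardization,
    bounding-box annotations with CSV persistence, box-aware data
    augmentation (translation, zoom, rotation, gamma contrast) and
    minority-class balancing, a trainable sliding-window valve detector,
    a threshold-binarization calcium heuristic and a trainable
    calcification classifier, IoU-based detection and classification
    metrics, and a seeded synthetic echocardiogram generator so the whole
    pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    png,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
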