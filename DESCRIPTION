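Package: fetalbiom
Title: Fetal Head Segmentation, Biometry and Growth Classification from
    Ultrasound-Like Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully testable pipeline for automated fetal head
    assessment from 2-D ultrasound-like images: a speckle phantom generator
    with analytic ground truth, image and mask preprocessing, a CPU
    implementation of an optimized SegNet encoder-decoder segmenter trained
    with a hybrid binary cross-entropy plus soft-Dice loss (Adam,
    reduce-on-plateau scheduling, best-checkpoint saving), segmentation
    quality metrics, head-circumference and biparietal-diameter measurement
    by least-squares ellipse fitting of the predicted mask contour, and
    rule-based microcephaly / normal / macrocephaly classification against a
    gestational-age reference table of means and standard deviations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
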