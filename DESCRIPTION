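Package: gwoscreen
Title: Glaucoma Screening with a Grey-Wolf-Tuned UNet++ Segmenter and a
    Capsule-Network Classifier
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An automated glaucoma-screening toolkit for retinal fundus
    photographs. A Grey Wolf Optimization (GWO) engine -- with both the
    canonical update rules and a variant coefficient schedule -- tunes the
    hyperparameters of a UNet++ optic-disc/optic-cup segmenter through a
    texture-differentiation fitness; the segmented disc region is then
    classified as glaucomatous or normal by a capsule network with dynamic
    routing-by-agreement. A seeded synthetic fundus generator produces
    disc/cup ground truth and class labels so that every stage of the
    pipeline is testable at desk scale without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
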