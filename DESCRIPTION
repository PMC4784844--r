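Package: hpcfill
Type: Package
Title: Hierarchical Predictive Coding and Perceptual Filling-In at the Blind Spot
Version: 1.0.0
Authors@R: person("hpcfill", "maintainers", email = "hpcfill@example.org",
    role = c("aut", "cre"))
Description: A three-level (LGN-V1-V2) hierarchical predictive coding network
    for studying perceptual filling-in at the retinal blind spot. The package
    trains sparse-coding efficacy matrices on whitened natural-image patches,
    lesions the feed-forward error pathway over a central 8x8 blind-spot
    region, and runs bar-stimulus experiments that probe the nonlinear
    response elevation, AND-gate behaviour, and misalignment tolerance of
    blind-spot completion. Includes generators for surrogate natural images
    (1/f noise plus occluding oriented segments) and for the bar-stimulus
    batteries, inference by energy-descent relaxation, Hebbian-style basis
    learning with gain adaptation, and quantitative read-outs (response
    profiles, completion index, percept similarity).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
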