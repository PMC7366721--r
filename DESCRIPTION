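Package: orbitometry
Title: Agreement Statistics and Simulation for Physical and Virtual-Reality Orbitometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Validation toolkit for comparing repeated anatomical diameter
    measurements made with a physical caliper against measurements made with a
    digital caliper in a virtual-reality rendering of the same computed
    tomography volume. Provides a synthetic CT skull phantom with metal bead
    and pin fiducials at known positions, a digital caliper with fiducial
    detection and refinement logging, a simulator of blinded repeated grader
    measurements with world-specific bias and location-dependent noise, and
    the agreement-statistics suite used in such validation studies: two-way
    intraclass correlation coefficients (agreement and consistency, single
    and average, with F-based confidence intervals), Bland-Altman limits of
    agreement, the Williams index with an angular-similarity kernel, Welch's
    t-test, variance-ratio tests and Cohen's d with effect-size categories,
    and per-location and group summary tables with percent increases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
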