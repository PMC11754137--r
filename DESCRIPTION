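Package: prbtomo
Title: Speed-of-Sound Tomography from Scanned Photoacoustic Beacons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Cross-sectional speed-of-sound (SOS) tomography for ring-array
    photoacoustic systems using scanned photoacoustic reversal beacons (PRBs).
    Provides beacon arrival-time picking from channel-time sinograms with a
    dynamic-programming tracker, a straight-ray travel-time forward model with
    a sparse path operator, L2-regularized inversion of the slowness deficit
    by Nesterov's accelerated gradient method, and acoustically corrected
    photoacoustic image reconstruction by multi-SOS delay-and-sum with
    coarse-grid time-of-flight computation and bicubic upsampling (TI-MDAS).
    A synthetic-data subsystem generates SOS phantoms, beacon sinograms and
    eikonal (fast-marching) first-arrival travel times so the whole pipeline
    can be exercised and validated without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    generics,
    Matrix,
    Rcpp,
    jsonlite,
    tibble,
    yaml,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse
Config/testthat/edition: 3
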