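Package: quadmap
Title: Quadruple-Parametric Cardiac FRET and Optical Mapping Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for multiparametric whole-heart fluorescence
    imaging that interleaves slow ratiometric CFP/YFP FRET acquisition (a
    cAMP biosensor readout) with high-rate optical mapping bursts of
    transmembrane potential and intracellular calcium. Provides pixel-wise
    FRET ratio (R = CFP/YFP) and normalized dFRET = R/R0 maps with ROI time
    courses and bolus-response metrics; spatially filtered, top-hat
    baseline-corrected optical action potential and calcium transient
    analysis (activation time at maximum upstroke derivative, APD80 and
    CaTD50 duration maps averaged over consecutive beats, heart rate,
    earliest-activation pacemaker localization); spectral bleed-through
    quantification and Kolmogorov-Smirnov trace comparison; fiducial-based
    similarity registration between camera grids with ROI colocalization and
    regional statistics; and a synthetic recording generator with analytic
    ground truth that emulates the interleaved acquisition schedule, focal
    activation wavefronts, regional response heterogeneity, vignetting,
    channel bleed-through and photon noise, so every analysis stage is
    verifiable against a known oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    tools,
    mgcv,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
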