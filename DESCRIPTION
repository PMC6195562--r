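Package: pavservo
Title: Photoacoustic Visual Servoing Simulator for Needle-Tip Tracking
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Desk-scale simulator and analysis library for robotic
    photoacoustic guidance of needle tips. Generates seeded synthetic
    photoacoustic channel data for a fiber-tip source in configurable
    tissue media (including electronic noise and acoustic clutter),
    beamforms it with receive-only delay-and-sum, segments the needle tip
    with a dynamic-threshold/morphology/connected-component pipeline with
    five-frame spatiotemporal consensus, and closes the loop with a
    probe-centering controller plus a back-and-forth search for recovery
    from out-of-plane motion. Ships harnesses for needle tracking, probe
    centering, angled-insertion/perturbation recovery, and fluence-sweep
    image-quality studies with contrast, SNR and channel-SNR statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
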