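Package: octspeckle
Title: Estimating Tissue Optical Properties from OCT Speckle via
    Monte-Carlo Look-Up Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Monte-Carlo simulation of optical coherence tomography (OCT)
    speckle in layered scattering tissue, and look-up-table inversion of
    the speckle statistics for the scattering coefficient and scattering
    anisotropy factor of corneal stroma. A compiled photon-packet
    transport core (Henyey-Greenstein scattering, Fresnel boundaries,
    disc detector) feeds a coherence-gated phasor-sum A-scan synthesizer;
    simulated B-scans over a (mu_s, g) parameter grid form a
    multi-reference look-up map, and an unknown B-scan's speckle contrast
    ratio and kernel density estimate are matched to the map with an
    ensemble of three distance measures whose minimizers are averaged
    into the final estimate.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    jsonlite,
    yaml,
    png,
    tiff,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
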