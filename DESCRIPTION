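Package: gadodose
Title: Gadolinium Spectral Response as a Dose Surrogate in Scanning Proton Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation study of gadolinium characteristic x-ray
    emission as a surrogate for in-vivo dose during pencil-beam-scanned proton
    therapy. Provides material and voxel-phantom definitions (water body,
    Dotarem-filled target), an analytic proton pencil-beam dose engine
    (Bragg-Kleeman range-energy model, range straggling, lateral Gaussian
    spread, water-equivalent ray tracing), a treatment planner (energy-layer
    selection, 3 mm spot lattice, nonnegative least-squares weight optimization
    to a uniform prescription), a two-channel 43 keV photon emission model
    (proton-induced K-shell x-ray emission and thermal-neutron capture on
    Gd-155/Gd-157) with attenuation-aware detection on a scoring sphere, a
    displacement scenario engine, and the dose-signal tracking analysis
    (per-spot correlations, DVH metrics, percent-change tables, cumulative
    treatment tracking).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    pracma,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
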