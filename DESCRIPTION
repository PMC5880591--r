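Package: epidose
Title: EPID Transit In-Vivo Dosimetry with Finite Tissue Maximum Ratios
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Commissioning and point-dose reconstruction for electronic portal
    imaging device (EPID) based in-vivo dosimetry. Builds finite tissue maximum
    ratio (fTMR) and conversion-factor tables from commissioning measurements,
    converts integrated portal-image signals (calibrated units) into dose at
    points of interest inside a phantom via the fTMR formalism and inverse
    square projection, and evaluates per-beam and per-point deviations against
    treatment planning system reference doses with clinical thresholds. A
    virtual-linac forward model generates commissioning records, portal images
    and reference doses so the whole chain is testable without measured data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
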