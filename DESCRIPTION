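Package: nirsda
Title: Near-Infrared Spectral Classification of Plant Varieties with PLS-DA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometric workflow for discriminating closely related plant
    varieties from near-infrared (NIR) leaf spectra. Implements standard
    normal variate (SNV) and Savitzky-Golay derivative preprocessing,
    per-class Kennard-Stone calibration/test splitting, multi-class PLS-DA
    (NIPALS PLS-2) with venetian-blinds cross-validated latent-variable
    selection, variable-importance statistics (VIP, target-projection
    selectivity ratio, regression vector), importance-driven spectral
    truncation, and per-class sensitivity/specificity/accuracy reporting.
    Ships a hierarchical synthetic leaf-spectrum generator (six varieties,
    fresh and dried-powdered modes) so the full pipeline is testable
    without instrument data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
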