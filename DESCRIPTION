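Package: tracequant
Title: Whole-Brain Retrograde Tracing Quantification
Version: 0.1.0
Authors@R:
    person("Trace", "Quant", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for two-channel monosynaptic rabies
    tracing histology: synthetic section simulation, fluorescent cell
    detection with size/roundness/SNR filters, two-channel starter
    classification by centroid overlap, landmark-based affine registration
    to 2-D atlas label masks, region-wise starter/presynaptic count tables
    with quality-control gates, connectivity metrics (presynaptic-per-
    starter, fraction-per-region, starter distribution), and per-region
    male-versus-female comparison with exact Wilcoxon-Mann-Whitney tests
    under Benjamini-Hochberg FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
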