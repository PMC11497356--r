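Package: nanotoxkin
Title: Dissolution-Based Toxicokinetics and Grouping of Soluble Metallic Nanoforms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Models the time-dependent partitioning of a suspension of
    soluble spherical metallic nanoforms into remaining particles and
    released ions (shrinking-sphere dissolution kinetics), combines Hill
    concentration-response curves for ions and particles under response
    addition to obtain the fraction of suspension toxicity attributable
    to ions, and locates the dimensionless dissolution-progress (Pt)
    boundaries that separate ion-dominated, mixed, and particle-dominated
    regimes.  Provides critical-value inversions (dissolution rate
    constant, exposure time, diameter, density), reference regime
    thresholds for three Hill-coefficient scenarios, reproduction of the
    silver/copper critical-rate tables, and a command-line interface for
    classification and screening of nanoforms in regulatory read-across.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
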