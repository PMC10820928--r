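Package: bmcscreen
Title: Benchmark Concentration Analysis for Plate-Based Zebrafish Embryo Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-laboratory zebrafish embryo
    developmental toxicity screens. Converts well-level screening records
    (mortality at 24 and 120 hours post fertilization, phenotypic
    alterations at 120 hpf) into per-plate incidence dose-response curves,
    estimates benchmark concentrations (BMC) by binomial bootstrap
    resampling with monotonic noise filtering and a benchmark-response
    threshold, makes activity calls from the fraction of non-noise
    bootstrap curves, and aggregates plate-level results into
    interlaboratory summaries: median potencies, duplicate-substance
    reproducibility, activity-call concordance, and potency rankings.
    Includes a synthetic multi-laboratory study generator with analytic
    ground truth for validation, plate-level quality control on vehicle
    controls, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
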