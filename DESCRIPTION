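Package: nitroniche
Title: Nitrification Rates, Single-Cell Isotope Probing and Marker-Gene
    Quantification for Marine Ammonia Oxidizers
Version: 0.1.0
Authors@R:
    person("Repository", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for comparative studies of marine ammonia- and
    urea-oxidizing communities. Estimates ammonia and urea oxidation rates
    from 15N dual-tracer incubation time series (linear-slope regression,
    one-sided significance testing, labeling-fraction correction,
    detection-limit censoring and duplicate reconciliation); quantifies
    single-cell 15N enrichment from NanoSIMS region-of-interest ion counts
    (ratio accumulation, Poisson counting-error and background quality
    control, detection limits, atom-percent excess and N-based growth
    rates); classifies reads against custom marker-gene databases with the
    BLAST-score-ratio criterion and quantifies genes as RPKM with
    taxon-group gene ratios and probe-coverage scoring; and computes
    niche-differentiation statistics (urea-N fractions, exact
    Mann-Whitney-Wilcoxon tests, boxplot summaries). A synthetic-data
    module generates all pipeline inputs with known ground truth so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
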