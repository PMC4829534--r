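Package: txturnover
Title: Comparative Analysis of Transcriptome Coverage Turnover Across Taxa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based comparative analysis of poly-A+ transcriptome
    coverage across closely related taxa mapped to a shared reference
    genome. Builds fixed 200-bp window count matrices from aligned fragment
    intervals, restricts analyses to a common genome detectable in all
    taxa, normalizes samples by subsampling reads without replacement, and
    derives presence/absence profiles at configurable read thresholds.
    Downstream analyses cover sharing classes of transcribed windows,
    transcriptome-sharing distance trees (phi correlation, Manhattan
    distances, neighbor joining with bootstrap supports and a
    sampling-variance partition of terminal branches), rarefaction over
    taxa and sequencing depth with logarithmic versus asymptotic
    saturation model selection by BIC and Bayes factors, run-length
    analysis of transcribed and non-transcribed regions, and
    permutation-based annotation enrichment. A phylogenetic turnover
    simulator (two-state Markov gain/loss along a tree, conserved
    high-expression core, log-normal expression, Poisson read sampling)
    provides synthetic data with full ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
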