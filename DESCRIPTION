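Package: m6Aarray
Title: Analysis of m6A Epitranscriptomic Two-Channel Microarrays
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantification and differential analysis of m6A RNA methylation
    from two-channel MeRIP microarrays. Raw Cy5 (immunoprecipitated, IP) and
    Cy3 (supernatant, Sup) probe intensities are calibrated against spike-in
    controls, filtered on Present/Marginal/Absent detection flags, and
    converted to the %Modified methylation-level statistic IP/(IP + Sup).
    Downstream stages provide two-group differential methylation (t-test,
    log2 fold change, Benjamini-Hochberg FDR within RNA biotype),
    Fisher-exact gene-set over-representation against GMT libraries,
    hierarchical clustering with heatmap and volcano rendering, and a
    ground-truth synthetic array generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    S4Vectors,
    SummarizedExperiment,
    ggplot2,
    pheatmap,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
biocViews: Epitranscriptomics, Microarray, DifferentialMethylation,
    TwoChannel, QualityControl, GeneSetEnrichment, Clustering
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
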