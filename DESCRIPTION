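Package: compobench
Title: Compositionality Effects on Microbiome Differential-Abundance
    Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation framework quantifying how the compositional nature
    of amplicon sequencing data distorts differential-abundance detection
    and multivariate variance partitioning.  Generates ground-truth
    absolute-abundance communities for a two-arm, two-timepoint
    intervention, simulates multinomial read sampling, applies four
    normalizations (relative abundance, centered log-ratio, TMM,
    median-of-ratios size factors), detects responding taxa with
    Kruskal-Wallis tests under Benjamini-Hochberg correction, and compares
    false-positive/false-negative rates and PERMANOVA variance explained
    (log-Pearson, Bray-Curtis and Aitchison distances) against the
    un-transformed absolute abundances across a grid of effect sizes and
    response proportions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    edgeR,
    vegan,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    optparse
Config/testthat/edition: 3
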