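Package: eqtlHotspots
Title: Integrative eQTL Mapping, Trans-eQTL Hotspot Detection and
    Genotype-Stratified Co-Expression Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative expression quantitative trait locus (eQTL)
    analysis toolkit: genome-wide additive SNP-gene association with
    fixed-effect covariates, cis/trans classification with per-class
    Benjamini-Hochberg FDR, permutation-based trans-eQTL hotspot detection
    with linkage-disequilibrium refinement and 4 Mb hotspot windows,
    permutation tests for overlap between eQTL regions and known QTL region
    sets, hotspot-genotype ANOVA on phenotypes, position-specific scoring
    matrix (PSSM) promoter scanning with exact score p-values,
    genotype-stratified weighted co-expression networks (soft-power
    adjacency, topological overlap, dynamic tree cut, module eigengenes,
    module-trait correlation, hub genes) and hypergeometric gene-set
    enrichment. A synthetic-data generator plants cis effects, a
    transcription-factor-mediated trans hotspot, covariates, module-coupled
    traits and promoter motif occurrences so that every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    vcfR,
    fgsea,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
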