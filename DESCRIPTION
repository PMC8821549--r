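Package: trbound
Title: Consensus ChIP-Seq Identification of Thyroid Hormone Receptor
    Target Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for identifying direct thyroid hormone receptor (TR)
    target genes from replicated ChIP-Seq experiments, modelled on the
    design of T3-induced intestinal remodeling studies in Xenopus:
    replicate-consensus peak determination by per-base intersection, a
    simplified Poisson pileup peak caller for simulated fragments,
    peak-to-gene assignment through gene-body windows extended by a
    flanking region, scanning for DR4 thyroid-hormone response elements
    ((A/G)GGTCA direct repeats with a 4-base spacer), Venn and overlap
    analytics linking TR binding to T3-regulated expression, and
    hypergeometric term enrichment with Benjamini-Hochberg FDR including
    genotype-differential (subtraction) enrichment. A seeded synthetic
    data generator produces a genome, annotation, noisy replicate peak
    sets for two genotypes by two treatments, and a linked expression
    table with a machine-readable truth record for parameter-recovery
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
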