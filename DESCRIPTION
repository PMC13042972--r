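Package: editomeKit
Title: Detection, Quantification and Genetic Mapping of A-to-I RNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building an RNA editome from RNA-seq mismatch pileups
    without matched DNA: a genome self-similarity mask to remove alignment
    artifacts, a multi-step filter cascade with strand correction, editing
    level quantification and tissue-specificity measures, co-editing module
    detection, cis editing QTL (edQTL) mapping with permutation-based
    empirical p-values, paired allele-specific editing tests, GWAS
    integration (matched-control enrichment, LD clumping, approximate Bayes
    factor colocalization, REML heritability partitioning) and cross-species
    conservation through chain-file coordinate lifting. Includes a seeded
    synthetic-data generator with planted ground truth so the full pipeline
    can be exercised and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    data.table,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    VariantAnnotation
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
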