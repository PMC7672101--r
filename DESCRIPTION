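Package: mutscape
Title: Somatic Mutation Landscape Analysis for Repair-Deficient Tumor Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing the genome-wide landscape of somatic mutations
    in DNA-repair-deficient tumors. Reads and filters somatic mutation catalogs
    (per-strand read support, variant allele frequency, mappability and
    blacklist masks), classifies mutations into the standard SBS96/DBS78/ID83
    channel schemes, extracts de novo mutational signatures by
    Kullback-Leibler non-negative matrix factorization and refits exposures by
    non-negative least squares with bootstrap confidence intervals, quantifies
    transcriptional and replicational strand asymmetries together with
    replication-timing and chromatin covariates, tests for clustered
    mutations against a context-preserving Monte Carlo null, and times
    mutations relative to copy-number events from variant allele frequencies.
    A synthetic-data module generates genomes, annotation tracks and mutation
    catalogs with known ground truth so every analysis is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    methods,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    pracma,
    ape
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
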