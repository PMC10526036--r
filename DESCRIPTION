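Package: woolscan
Title: Composite Selection-Signature Scans in Two-Population Resequencing Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects selective sweeps between two cohorts of resequenced
    diploids by combining three window-based statistics: Weir-Cockerham Fst,
    the nucleotide-diversity ratio (theta-pi ratio), and cross-population
    extended haplotype homozygosity (XP-EHH). Implements the full workflow
    from phased VCF input through SNP quality control, LD pruning, population
    structure summaries (identity-by-state distances, PCA, neighbor-joining
    trees), windowed scans with top-fraction thresholding, candidate-region
    flanking and gene annotation against GFF3 models, gene-set intersection,
    and exact hypergeometric term enrichment. A two-population sweep
    simulator with Balding-Nichols allele frequencies generates fully
    reproducible phased datasets with planted sweeps, so every stage is
    testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    methods,
    vcfR,
    ape,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
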