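Package: pollenDMR
Title: Methylome Comparison and Allele Transmission Analysis for Pollen
    Cell Types
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to compare whole-genome bisulfite methylomes of pollen
    cell types (vegetative versus sperm cells) in plants. Implements
    context-aware (CG/CHG/CHH) differentially methylated region calling on
    fixed 50-bp bins with per-context site-count and difference thresholds
    and 400-bp merging, association of regions with gene and transposable
    element annotations, Fisher's exact enrichment of gene sets, and
    quantification of mutant-allele transmission through pollen with exact
    binomial and Welch tests. A synthetic bisulfite-methylome generator
    with planted demethylated regions and heterozygote pollen-pool
    mixtures makes the full pipeline testable without external data.
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
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
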