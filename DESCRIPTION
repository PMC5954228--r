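Package: fiscog
Title: Distilling Fungus-Insect Symbiotic Core Genes from Comparative Proteomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for distilling a fungus-insect symbiotic core
    gene (FISCoG) toolbox from commensal, entomopathogenic and free-living
    fungal proteomes. Provides a Smith-Waterman local aligner with
    Karlin-Altschul statistics and BLAST tabular import/export, reciprocal
    best hit and Markov (MCL) ortholog clustering with connectivity-based
    representative selection, missing-taxon-tolerant core gene sets, Venn
    partitions and negative-control subtraction, supermatrix preparation
    with partition bookkeeping, allele-frequency-spectrum ploidy inference
    from per-site read counts, whole-genome match-identity aggregation and
    assembly statistics. A synthetic-data module generates multi-taxon
    proteomes with planted symbiosis-core families and haploid/diploid read
    pileups with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
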