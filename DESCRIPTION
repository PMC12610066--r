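Package: germsnp
Title: SNP-Based Germplasm Characterization: Diversity, Structure,
    Fingerprinting and Double-Digest Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing plant germplasm panels from genome-wide
    SNP genotypes: simulation of structured, admixed diploid genotype data;
    VCF import and locus filtering on minor allele frequency and locus
    integrity; per-population genetic diversity indices (MAF, Ne, He, Nei's
    H, Na, Ho, PIC, Shannon-Wiener I); neighbor-joining phylogeny on
    p-distances with bootstrap support; genotype PCA and a genomic
    relationship matrix; concordance analysis between alternative sample
    groupings; selection of core SNP markers and color-coded DNA
    fingerprint barcodes; and in silico double-digest simulation for
    reduced-representation (SLAF-style) library design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    igraph,
    seqinr,
    stats,
    utils,
    vcfR
Suggests:
    cluster,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
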