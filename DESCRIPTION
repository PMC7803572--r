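Package: methkin
Title: Kinship-Aware Differential Methylation Analysis for WGBS Count Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for whole-genome bisulfite sequencing (WGBS) methylome
    analysis in pedigreed study designs: CpG coverage filtering, sequence- and
    annotation-derived CpG context (CpG islands, shores, shelves, genic class,
    promoters), differential methylation testing by a beta-posterior
    minimum-difference criterion and by a binomial generalized linear mixed
    model with a pedigree kinship random effect fitted via penalized
    quasi-likelihood, merging of differential cytosines into regions,
    detection of pedigree-shared (inheritable) methylation regions with a
    genome-wide corrected binomial false-positive bound, and integration of
    promoter methylation with gene expression. Includes a synthetic-data
    generator that emulates a two-tissue, two-breed, multi-age pedigreed
    design with planted effects and ground-truth tables for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    BiocGenerics,
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    pracma,
    jsonlite,
    stats,
    graphics,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
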