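Package: corealign
Title: Guide-Tree-Free Progressive Core-Genome Alignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and aligns the core genome of a set of assemblies by
    progressive pairwise alignment without a guide tree. A single query genome
    is aligned to each subject in turn; high-scoring segment pairs are ordered,
    filtered for overlap, merged, and checked for synteny and (optionally)
    chromosome homology before the surviving query consensus is carried to the
    next subject. A backtracking step threads every subject row back through
    the iteration stack to reconstruct a multi-genome core alignment in MAF and
    multi-FASTA form, from which Jukes-Cantor distances, neighbor-joining trees
    and core-genome summary statistics are derived. A genome-population
    simulator with known core/accessory structure supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    ape,
    phangorn,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
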