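Package: orthophylo
Title: Transcriptome Orthologue Phylogenomics and Floral Gene Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale phylogenomic pipeline for multi-species transcript
    sets. Builds single-copy orthologue clusters by filtered reciprocal-unique
    local-alignment search anchored on two reference gene sets, aligns and
    concatenates clusters into a gap-stripped supermatrix, estimates per-gene
    and concatenated neighbor-joining trees with bootstrap support and
    majority-rule consensus, counts gene-tree support for competing species
    topologies (with truncated-percentage reporting), and identifies and
    classifies MADS-box floral gene copies into ABCDE/SOC/SVP families via
    anchored gene trees. Includes a seeded synthetic-data generator (species
    trees, concordant and discordant gene trees, HKY-evolved coding sequences,
    transcript sets with paralogue and near-duplicate noise, and a labeled
    MADS-like protein family) so every stage is testable without raw reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
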