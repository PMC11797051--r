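Package: asvassembly
Title: Community Assembly Analysis for Amplicon Sequence Variant Tables
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for inferring the ecological processes that
    structure host-associated and aquatic microbial communities from 16S
    amplicon sequence variant (ASV) tables. Provides quality filtering
    (low-abundance and negative-control contaminant removal), total-count
    scaling normalization, alpha diversity (richness, Chao1, Hill number of
    order one, evenness), Bray-Curtis beta diversity with principal
    coordinates analysis, one-way PERMANOVA and SIMPER, phylogenetic
    null models (nearest taxon index NTI and its between-sample analogue
    beta-NTI) that partition community assembly into selection and
    stochasticity, and a synthetic-data generator that assembles communities
    on a simulated phylogeny under known processes so that every stage of
    the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    vegan,
    stats,
    utils
Suggests:
    picante,
    jsonlite,
    igraph,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
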