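Package: sgbstrain
Title: Species-Level Genome Bins and Subspecies Resolution for Gut Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Strain-resolution and functional-screening toolkit for insect gut
    metagenome collections. Estimates pairwise genome distances with bottom-s
    MinHash sketches of canonical k-mers (Mash-style), dereplicates
    metagenome-assembled genomes into species-level genome bins (SGBs) by
    average-linkage clustering at a 5% distance cut, classifies bins against a
    reference collection as known or unknown with rank-level placement, and
    resolves within-SGB subspecies by fragment-based average nucleotide
    identity, partitioning around medoids and a prediction-strength criterion.
    Also provides homology-hit filtering and RPKM quantification for functional
    gene screening, community statistics (binary Jaccard distances, PERMANOVA,
    alpha diversity, pairwise Wilcoxon tests), and seeded synthetic-data
    generators that plant known species, subspecies and group-effect structure
    for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    cluster,
    vegan,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
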