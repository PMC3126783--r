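Package: seedcoex
Title: Coexpression Networks, Fuzzy Clustering and Promoter Motifs for
    Seed Development Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for transcriptome time courses of
    developing seeds: expressed-gene filtering and stage-median
    summarisation of replicated log2 expression matrices, sample-level
    PCA and a permutation test of stage association, Pearson-threshold
    gene coexpression networks with scale-free topology diagnostics
    (clustering coefficient, power-law exponent, degree histograms),
    fuzzy c-means clustering of standardized temporal profiles with
    membership cores, and promoter cis-element analysis (position
    weight matrix scanning on both strands, Markov-background false
    discovery rate calling, two-scanner consensus, and mean-plus-SD
    overrepresentation).  A synthetic-data generator with planted
    cluster and motif ground truth makes every stage testable.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    igraph,
    stats,
    utils
Suggests:
    e1071,
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
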