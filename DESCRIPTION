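Package: MetaCAZ
Title: Tiled Translated Profiling and Comparison of Carbohydrate-Active
    Gene Families in Assembled Metagenomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Functional profiling of assembled metagenomes by overlapping-tile
    translated homology search against family-labeled protein databases
    emulating CAZy (carbohydrate-active enzymes) and FOLy (lignin oxidases).
    Contigs are divided into overlapping 300 nt tiles, each tile is searched
    against the protein database by six-frame Smith-Waterman alignment, best
    hits per tile are collected into contiguous same-family runs, and run
    lengths are weighted by mean contig depth and normalized to nucleotides
    per million depth-weighted nucleotides. Includes composition-based contig
    binning into population bins via trinucleotide-frequency centroids,
    cross-metagenome comparison by Spearman correlation distance (UPGMA
    clustering and classical MDS), and a synthetic-metagenome simulator with
    planted gene families that provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    ape,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
biocViews: Metagenomics, Sequencing, Classification, Clustering
RoxygenNote: 7.3.3
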