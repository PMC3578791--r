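Package: protistdiv
Title: Clustering Patterns and Phylogenetic Structure of Marine
    Microeukaryote 18S rDNA
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Characterizes the genetic diversity of taxonomic groups of
    marine microbial eukaryotes from aligned 18S rDNA sequences and rooted
    phylogenies. Computes Jukes-Cantor pairwise distance matrices, clusters
    sequences into OTUs by furthest-neighbor (complete-linkage)
    agglomeration on a fixed precision grid, and summarizes each group by
    its average, maximum, and maximum corrected distance (the smallest
    cutoff at which 90 percent of sequences fall in one OTU) together with
    OTU counts across cutoffs. Calibrates partial-gene regions (e.g. V4-V5)
    against full-gene distances by regression, and describes tree shape via
    standardized lineage-through-time curves, the gamma statistic with a
    one-tailed constant-rate test, mean phylogenetic distance, and the
    trunk (stem) length of monophyletic groups. Includes a synthetic-data
    module (Yule trees, time warping, Jukes-Cantor sequence evolution with
    region-specific rates) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    phangorn,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
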