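Package: gendiv
Title: Population Genomics on SNV Tables: Diversity, Differentiation,
    Sweep Intervals, Admixture Painting and Gene-Set Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-individual single-nucleotide-variant (SNV)
    tables in the gd_snp and gd_genotype formats: parsing, VCF conversion,
    filtering, aggregation and uniform subsampling; nucleotide diversity
    (pi and Watterson's theta), three F_ST estimators (Wright,
    Weir-Cockerham, Reich) and locus-specific branch lengths; window-free
    detection of high-scoring SNV runs by the all-maximal-scoring-segments
    algorithm with shuffle-based significance; penalized dynamic-programming
    painting of admixed genomes over two or three source populations;
    neighbor-joining trees from genotype distances; Fisher-exact gene-set
    enrichment, pathway path-disruption ranking and clustering of gene
    categories; and a synthetic-data generator producing populations with
    controllable differentiation, admixed individuals with known ancestry
    tracts, and pooled read counts.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    ape,
    igraph,
    vcfR,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
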