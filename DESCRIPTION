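Package: laminascan
Title: Genomic Clustering of Misexpressed Genes and 3D FISH Territory
    Quantification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline linking gene misexpression to chromosome
    mispositioning in laminopathy cells. Implements rank-products ranking of
    expression fold changes with a dual-normalization top-K intersection,
    sliding-window detection of genomic clusters of misexpressed genes with an
    empirical permutation null, per-chromosome misexpression enrichment with a
    chi-square test of uniformity, and a 3D fluorescence in situ hybridization
    (FISH) quantification engine: per-slice Euclidean distance maps, territory
    to nuclear-edge minimum distances with orthogonal reslicing, inter-locus
    distances, lamina-contact scoring, and territory volumes. Synthetic
    generators for annotated gene maps, paired expression tables, and
    multi-channel 3D nucleus stacks provide ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Matrix,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
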