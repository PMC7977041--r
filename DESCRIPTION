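Package: fossilflows
Title: Multilayer Network Delineation of Marine Mega-Assemblages from Fossil Occurrences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds weighted bipartite multilayer networks from stage-binned
    fossil occurrence data (genera linked to hexagonal grid cells, one layer
    per geological stage), clusters them with a relax-rate multilayer map
    equation and a deterministic Louvain-style codelength search, assesses
    module robustness with a truncated-Poisson parametric bootstrap, and
    computes the partition-comparison statistics (adjusted mutual
    information, Jaccard, Sorensen dissimilarity, alluvial overlap,
    dominance timelines) used to delineate Phanerozoic marine
    mega-assemblages and their biotic transitions. Includes a synthetic
    fossil-record generator with planted assemblage structure so the whole
    pipeline is testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    data.table,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
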