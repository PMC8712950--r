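Package: imacomplex
Title: Protein Complex Detection in Weighted PPI Networks with a Memetic Algorithm
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Detects protein complexes in protein-protein interaction (PPI)
    networks. Edges are weighted by combining four evidence sources
    (higher-order common neighbours, gene co-expression, GO-slim attribute
    similarity and subcellular co-localization); candidate complexes are then
    refined by a memetic algorithm that combines a genetic search over
    clusterings with a per-cluster local optimization of a five-term fitness
    function (cohesiveness, weighted density, average inner/border edge
    weight and weight-based modularity). Includes the standard evaluation
    suite for complex prediction (F-measure, coverage rate, Sn/PPV/ACC,
    maximum matching ratio, Jaccard, hypergeometric enrichment and
    co-localization scores) and a planted-complex synthetic benchmark
    generator with correlated attribute data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
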