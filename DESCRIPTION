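Package: soilgnn
Title: Multi-Scale Attention Graph Neural Networks for Soil Heavy-Metal Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Predicts soil heavy-metal (cadmium and lead) concentrations at
    georeferenced sampling sites with a multi-scale attention graph neural
    network. Builds spatial graphs from site coordinates by great-circle
    radius neighborhoods with Boolean-power reachability and connectivity
    repair, optionally masked by parent-material environmental type, and
    trains a regressor combining multi-hop normalized graph convolutions with
    softmax attention aggregation. Includes soil-survey table I/O and
    descriptive statistics, dissolved-organic-matter optical indices, density
    clustering of parent-material zones, nested and repeated-split evaluation
    with permutation feature importance, a synthetic survey generator with
    spatially autocorrelated fields, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    geosphere,
    ape,
    e1071
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
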