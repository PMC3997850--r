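Package: jamunet
Title: Supervised Clustering of Herbal Formula Networks for Plant-Disease Prediction
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts medicinal-plant to disease-class relations from a corpus
    of multi-ingredient herbal formulas (such as Indonesian Jamu). Formulas are
    compared by the fourfold point correlation (phi coefficient) of their binary
    ingredient vectors; the top fraction of pairs defines an undirected
    similarity network; overlapping dense clusters are extracted with a
    density-and-periphery growth algorithm (DPClusO-style) that guarantees node
    coverage; each cluster is assigned its dominant disease class by matching
    score and its highest-frequency plants, and the resulting (plant, disease)
    relations are scored against an efficacy gold standard by true-positive
    rate. Includes size-matched Erdos-Renyi, Barabasi-Albert and
    connecting-nearest-neighbour random-graph baselines, a synthetic corpus
    generator with planted plant-disease structure, and an end-to-end pipeline
    runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
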