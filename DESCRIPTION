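Package: kingdomnet
Title: Multi-Kingdom Co-Occurrence Network Inference and Stability Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for inferring and analysing signed co-occurrence networks
    that span several biological kingdoms (plants, nematodes, fungi, bacteria,
    archaea) from compositional count tables. Provides a sparse
    neighbourhood-selection estimator with StARS stability selection on
    per-kingdom centred log-ratio transforms, signed-network topology
    summaries, within-module degree z / participation coefficient node-role
    classification, natural-connectivity robustness analysis with kingdom
    addition and removal experiments, cross-kingdom link-preference statistics
    with Erdos-Renyi null ensembles, and multiple regression on distance
    matrices with permutation inference. A synthetic multi-kingdom data
    generator with known ground-truth association structure makes the whole
    pipeline testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
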