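Package: pillr
Title: Protein Function Prediction with Incomplete Hierarchical Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Replenishes missing hierarchical function labels of partially
    annotated proteins and predicts functions for unlabeled proteins. Combines
    a hierarchy-aware label similarity (ComSim, a switch between a
    shared-ancestor variant of Lin's information-content similarity and the
    Jaccard co-annotation coefficient) with graph-regularized label
    propagation over a protein-protein interaction network. Supports FunCat
    tree and Gene Ontology DAG label hierarchies, enforces the true path
    rule, simulates incomplete annotation by masking per-protein leaf labels,
    and evaluates predictions with standard multi-label metrics (MicroF1,
    MacroF1, AvgROC, ranking loss, Fmax).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
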