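Package: mnbdr
Title: Module-Network-Based Drug Repositioning from Expression Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Screens candidate drugs for diseases by mining dense modules
    from a protein-protein interaction network, linking modules into a
    module network via a permutation test on inter-module edge counts,
    ranking disease-relevant modules by damped network propagation of
    expression-derived importance scores, and scoring each drug against a
    disease with a rank-alignment indicator. Includes classic connectivity
    baselines (KS, Zhang, XSum), ROC / partial-AUC evaluation with
    permutation p-values, and a seeded synthetic-data generator for
    end-to-end benchmarking without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
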