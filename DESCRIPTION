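Package: combiscreen
Title: Machine-Learning-Guided Combinatorial Mutagenesis Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for machine-learning-assisted directed evolution (MLDE) of
    genome editors from focused combinatorial mutagenesis libraries. Covers
    enumeration of multi-site combinatorial libraries and variant nomenclature,
    conversion of two-bin sort-seq barcode counts into enrichment scores and
    min-max-scaled fitness, randomized and diversity-constrained training-set
    sampling, physicochemical (Georgiev-style) and one-hot sequence encodings,
    an ensemble of regularized regression models with randomized hyperparameter
    search to predict fitness across the full in-silico library, and ranking
    and classification metrics (NDCG, top-k enrichment, precision, specificity,
    sensitivity, resource efficiency, capture rate) plus the T7 endonuclease-I
    editing-efficiency formula. A synthetic fitness-landscape and sort-seq
    screen simulator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    glmnet,
    ranger,
    seqinr,
    statmod,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
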