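Package: scstates
Title: Cell States, Metaprograms and Copy-Number Inference for Tumor Single-Cell RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidy pipeline for dissecting intratumoral heterogeneity in
    single-cell RNA-seq of brain tumors such as ependymoma. From a genes-by-cells
    expression matrix it applies the standard log2(TPM/10+1) transform and
    quality-control filters, infers smoothed copy-number profiles from relative
    expression with a 100-gene sliding window, classifies cells as malignant or
    normal by combining copy-number calls with marker-based cluster labels,
    discovers per-sample expression programs by non-negative matrix factorization
    and merges correlated programs into metaprograms, scores cells against
    expression-matched control gene sets, assigns cell states and cycling status,
    compares programs across anatomical compartments and tumor types, aggregates
    binarized regulon activity per cell state, and stratifies bulk cohorts into
    high and low signature groups for Kaplan-Meier survival analysis. A
    synthetic-data generator with planted copy-number events, gene modules and
    survival effects makes every stage testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
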