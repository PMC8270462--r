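Package: sparsesigs
Title: Sparse Mutational Signature Discovery with a Fixed Background
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: De novo discovery of somatic mutational signatures by
    non-negative matrix factorization with a fixed, dense background
    signature representing replication-error ('clock-like') mutagenesis.
    Non-background signatures are regularized by a non-negative LASSO
    penalty whose weight is expressed as a fraction of the data-dependent
    maximal penalty, and the number of signatures and the penalty weight
    are selected jointly by repeated bi-cross-validation with iterative
    imputation of held-out matrix cells. Includes classification of
    single-nucleotide variants into the 96 trinucleotide-context
    categories, a synthetic-cohort simulator emulating published
    benchmark designs, and the evaluation metrics used to score
    signature and exposure recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    Rsamtools,
    GenomicRanges,
    IRanges,
    VariantAnnotation
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
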