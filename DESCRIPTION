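Package: mbfpath
Title: De Novo Cancer Driver Pathway Discovery with a Mouth Brooding
    Fish Metaheuristic
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate cancer driver pathways directly from a
    binary patient-by-gene somatic mutation matrix, without prior pathway
    knowledge. Gene sets of fixed size k are scored by a maximum weight
    submatrix objective that rewards patient coverage and penalizes
    co-occurring mutations, with per-gene penalties weighted by a fusion
    covariate built from gene expression level, replication timing, and
    chromosome status via principal component analysis. The objective is
    maximized by a Mouth Brooding Fish population metaheuristic with a
    cardinality-constrained top-k decoding, validated against an
    exhaustive-search oracle on small instances. Significance of an
    identified pathway is assessed by a permutation test that re-optimizes
    on matrices with per-gene mutations shuffled across patients. Includes
    synthetic-data generators (Bernoulli background matrices, planted
    high-coverage/high-exclusivity pathways, correlated covariates), TSV
    readers and writers for mutation, covariate, and result tables, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
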