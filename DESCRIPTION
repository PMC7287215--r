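Package: phasesig
Title: Phase-Signature Discovery in Blood Transcriptomes by Monte Carlo
    Feature Selection and Incremental Feature Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers multi-phase gene-expression signatures from bulk
    blood transcriptome matrices. Ranks genes by Monte Carlo feature
    selection (many information-gain decision trees grown on random
    feature subspaces, aggregated into a per-gene relative importance),
    selects a compact signature by incremental feature selection scored
    with leave-one-out cross-validated support vector machines, clusters
    signature genes into phase-associated expression programs, and tests
    the signature for gene-set over-representation with the
    hypergeometric distribution. Includes a synthetic three-phase
    expression-data generator with planted signatures for end-to-end
    parameter-recovery testing, plus readers and writers for expression,
    label, probe-map and GMT files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    class,
    e1071,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    pheatmap,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
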