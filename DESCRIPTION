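Package: ocrstats
Title: Case-Control Differential Chromatin Accessibility and Peri-Event
    Calcium Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical machinery for case-control studies of open chromatin
    regions (OCRs) and companion calcium-imaging readouts. Implements CPM
    filtering, TMM plus within-cell-type quantile normalization, a BIC-based
    covariate selection ledger, precision-weighted linear modelling of
    normalized accessibility with a subject-level consensus correlation,
    label-permutation and classifier-based validation of differential region
    sets, sample-identity QC (genetic sex inference, genotype concordance,
    PBC, FRiP), a circular-permutation peri-event modulation classifier for
    dF/F traces, and gene-set overlap, rescue and Jaccard-pruning statistics.
    Ships negative-binomial and AR(1) simulators with planted ground truth so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    Matrix,
    limma,
    edgeR,
    vcfR,
    fgsea,
    e1071,
    randomForest,
    nnet,
    class,
    pROC,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
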