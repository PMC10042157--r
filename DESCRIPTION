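Package: wlsig
Title: Weight-Loss Classification Signatures from Baseline Adipose Tissue RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers and evaluates gene-expression signatures that predict
    diet-induced weight-loss class (high versus low weight losers) from baseline
    subcutaneous adipose tissue RNA-seq. Implements the full resampled pipeline:
    negative-binomial differential expression adjusted for sex, age and study
    center; hypergeometric Gene Ontology over-representation with
    Benjamini-Hochberg control; Jaccard-similarity enrichment maps with
    redundancy collapse and connected-component pathway classes; PCA-based
    ten-gene signature extraction with cross-run frequency aggregation;
    linear support-vector-machine classification over Monte-Carlo 80/20
    resamples with TMM/log-CPM normalization computed independently in training
    and testing subsets; an empirical random-gene null for median AUC; DeLong
    confidence intervals; clinical-factor augmentation with paired-AUC
    comparison; and weight-trajectory diagnostics including regainer
    identification and the Jonckheere-Terpstra trend test. A synthetic cohort
    generator with matched ground truth makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    edgeR,
    igraph,
    jsonlite,
    Matrix
Suggests:
    testthat (>= 3.0.0),
    pROC,
    sva
Config/testthat/edition: 3
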