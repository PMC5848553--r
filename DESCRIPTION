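Package: ribotype
Title: Ribosomal Protein Transcript Expression Pattern Discovery in Tumor Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering and characterizing patterns of ribosomal
    protein transcript (RPT) expression in bulk RNA-seq tumor cohorts.
    Expression of the ~80 cytoplasmic ribosomal protein genes is converted to
    a compositional (relative) statistic, embedded with exact t-SNE under a
    calibrated-perplexity protocol, and clustered by density connectivity.
    Clusters are compared by per-gene ANOVA volcano tables and cluster-versus-
    rest Welch contrasts; co-regulated transcript sets recurring across cohorts
    are extracted; GISTIC-thresholded copy-number calls, categorical and
    continuous clinical covariates, and Kaplan-Meier survival are tested for
    cluster association; and tissue-of-origin / tumor-versus-normal
    classifiers (logistic regression and a ReLU feed-forward network with a
    hyperparameter sweep) are fit on cohort-balanced splits. A synthetic
    cohort generator with planted subcluster, amplicon, clinical and hazard
    structure provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    cluster,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
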