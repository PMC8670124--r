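Package: fedvoom
Title: Federated Privacy-Aware Differential Expression with Voom Precision Weights
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Federated differential gene expression analysis for RNA-seq read
    counts distributed across multiple cohorts. Clients holding private count
    matrices and design matrices jointly compute gene-level moderated
    t-statistics equivalent to a pooled limma-voom style analysis (gene
    filtering, upper-quartile normalization, log-CPM, mean-variance precision
    weights, weighted linear models, empirical-Bayes variance moderation)
    without exchanging raw expression values. Local model parameters are
    hidden from the aggregation server by a hybrid additive secret-sharing
    scheme: exact modular masking for integer parameters and Gaussian-noise
    masking for real parameters, with a separate non-colluding compensator
    party removing the aggregate noise. Also provides the classical
    meta-analysis baselines (Fisher, Stouffer, DerSimonian-Laird random
    effects, rank product), evaluation metrics against a pooled oracle, and a
    seeded negative-binomial count simulator with planted fold changes,
    covariates, batch effects and imbalanced cohort splits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    limma,
    edgeR,
    metafor,
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
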