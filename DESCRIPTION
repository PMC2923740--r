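Package: poolprot
Title: Pooled Case-Control Plasma Proteomics Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Differential-abundance inference for pooled case-control plasma
    proteomics experiments quantified by heavy/light isotope labeling.
    Rolls peptide-level heavy/light ratios up to protein-group log2
    case/control ratios per pool pair, median-centers each experiment,
    applies peptide-count and pool-pair exclusion rules, fits per-protein
    weighted linear models with disease-specific means and a label-swap
    covariate, moderates variances by empirical Bayes and controls the
    false discovery rate per disease. Also provides a regularized Hotelling
    T2 protein-set test with a sign-flip permutation null, replication
    statistics for matched-pair immunoassay data (geometric mean ratios,
    covariate-adjusted models, quartile logistic regression with trend
    test, fold-change-to-odds-ratio projection), and joins against
    treatment-effect tables to select concordant candidate mediators.
    A synthetic-data module generates pooled experiments with known truth
    so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    fgsea,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
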