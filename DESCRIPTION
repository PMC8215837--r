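Package: mrpipe
Title: Two-Sample Mendelian Randomisation, Multivariable MR and Cross-Trait
    LD Score Regression on GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for causal inference from GWAS summary statistics:
    reading and allele-harmonizing summary-statistic tables, greedy LD
    clumping for instrument selection, univariable two-sample Mendelian
    randomisation (fixed-effect IVW, MR-Egger, weighted median, mode-based
    and penalised-weight estimators), outlier-robust sensitivity analysis
    (an MR-PRESSO-style residual-sum-of-squares test and a contamination
    mixture estimator), multivariable MR with mediation and attenuation
    decomposition, bidirectional runs, cross-trait LD score regression
    with block-jackknife errors, and power analysis. A synthetic-data
    module simulates two-sample GWAS summary statistics under a known
    causal diagram with configurable pleiotropy, so every estimator can
    be exercised against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
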