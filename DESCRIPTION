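Package: tgmr
Title: Individual-Level One-Sample Mendelian Randomization for
    Triglycerides and Hypertension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for individual-level (one-sample) Mendelian
    randomization of log triglyceride levels on hypertension risk: genotype
    quality control (call rate, minor allele frequency, exact Hardy-Weinberg
    test, windowed LD pruning), an additive per-SNP exposure scan with a
    suggestive discovery threshold, prespecified instrument screening with an
    auditable exclusion trail, weighted and K-fold cross-fitted genetic risk
    scores, two-stage predictor substitution (2SPS), two-stage residual
    inclusion (2SRI) and linear two-stage least squares (2SLS) causal
    estimators with weak-instrument, Sargan overidentification and Wu-Hausman
    endogeneity diagnostics, bootstrap uncertainty, and the parallel
    observational arm (t and chi-square tests, covariate-adjusted comparisons,
    crude and adjusted logistic odds ratios). A synthetic-cohort generator
    emulating the statistical structure of a Korean health-check cohort makes
    every stage testable without access to individual-level data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
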