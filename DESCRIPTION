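Package: mrtriad
Title: Two-Step Mendelian Randomization Mediation Analysis of GWAS Summary
    Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating how much of a causal effect of a metabolic
    phenotype on a disease outcome is transmitted through an intermediate
    plasma metabolite, using only GWAS summary statistics. Implements
    instrument selection and allele harmonization, two-sample Mendelian
    randomization estimators (Wald ratio, inverse-variance weighted, MR-Egger,
    weighted median, and a Bayesian outlier-robust estimator), heterogeneity
    and pleiotropy diagnostics (Cochran's Q, Rucker's Q, an MR-PRESSO-style
    global and outlier test, leave-one-out), Bayesian colocalization with
    Wakefield approximate Bayes factors, a simplified LD-score regression for
    heritability and genetic correlation screening, product-of-coefficients
    mediation with delta-method intervals, and a configurable discovery
    pipeline with evidence tiering. A synthetic-data module generates summary
    statistics with known causal structure for calibration and
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
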