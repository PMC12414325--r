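Package: mrtwin
Title: Two-Sample Mendelian Randomization and Twin Direction-of-Causation
    Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Two complementary genetic causal-inference toolkits for
    brain-behaviour epidemiology. The first arm implements two-sample
    Mendelian randomization on GWAS summary statistics: instrument
    selection, allele harmonization with palindromic-SNP exclusion,
    Steiger directionality filtering, confounder exclusion lists, and an
    estimator battery comprising random-effects inverse-variance
    weighting, the weighted median, MR-Egger regression, leave-one-out
    diagnostics, PRESSO-style global heterogeneity and outlier tests, and
    constrained-maximum-likelihood MR with AIC/BIC model averaging. The
    second arm fits MR-DoC structural equation models to monozygotic and
    dizygotic twin pairs by full-information maximum likelihood, using a
    polygenic score as the instrument with an explicit horizontal
    pleiotropy path, an ACE variance decomposition, liability-threshold
    ordinal outcomes with fixed thresholds, sensitivity analysis over the
    fixed unique-environment covariance, and a PRS-free hybrid
    direction-of-causation model. Seeded synthetic-data generators for
    both arms provide known ground truth for testing and calibration.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
Depends: R (>= 4.0)
Imports:
    jsonlite,
    lme4,
    mvtnorm,
    stats,
    utils
Suggests:
    knitr,
    numDeriv,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
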