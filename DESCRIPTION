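Package: mrmediate
Title: Bidirectional Two-Sample Mendelian Randomization and Two-Step Mediation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A complete two-sample Mendelian randomization (MR) workflow for
    GWAS summary statistics: instrument selection (significance thresholding,
    greedy LD clumping, confounder exclusion lists, per-SNP R-squared and
    F-statistic filters), effect-allele harmonization with palindrome removal,
    five causal-effect estimators (Wald ratio, fixed/random-effects
    inverse-variance weighted, MR-Egger, weighted median, mode-based), a
    sensitivity battery (Cochran's Q, Egger intercept, MR-PRESSO outlier
    detection, leave-one-out, Steiger directionality), Benjamini-Hochberg FDR
    across exposure panels, and two-step mediation via the product of
    coefficients with mediated proportions. Includes a synthetic GWAS
    summary-statistics generator with known ground truth so the whole pipeline
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
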