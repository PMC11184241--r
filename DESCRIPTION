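Package: cyberface
Title: Facial-Expression Pattern and AUC Analysis for Cyberball
    Social-Exclusion Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for frame-level facial emotion-intensity
    logs (FaceReader-style exports) recorded while participants play the
    Cyberball social inclusion/exclusion paradigm. Reads and validates
    per-frame intensity streams for the seven primary emotions, applies
    the software's continuous-calibration equations, aggregates to
    per-second scores, derives group dominant-emotion percentage patterns
    and their 10-interval summaries, compares patterns against a
    second-by-second shuffled white-noise null, computes trapezium-rule
    areas under the curve (standardized across frame rates) with
    happiness-masking sums, and runs the inferential layer: paired t and
    Wilcoxon signed-rank tests, two-way repeated-measures ANOVA with
    normalizing transforms and extreme-outlier screening, Spearman
    correlation matrices, and Benjamini-Hochberg/Bonferroni corrections.
    A seeded synthetic-cohort generator (latent logistic AR(1) intensity
    streams plus a Gaussian copula for clinical-scale scores) makes the
    whole pipeline testable without patient recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    car,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
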