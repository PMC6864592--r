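Package: avfuse
Title: Audiovisual Cue Integration Analysis with Constrained Psychometric Fitting
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates two-interval forced-choice (2IFC) audiovisual spatial
    localization experiments for model observers (maximum-likelihood fusion,
    cue switching, fixed-weight), fits constrained cumulative-Gaussian
    psychometric functions under binomial or betabinomial likelihoods with a
    shared lapse rate and overdispersion scale, derives maximum-likelihood
    cue-integration predictions (sensory weights, fused variance, conflict
    PSEs), and provides parametric-bootstrap goodness-of-fit and contrast
    tests plus a group-level inference battery (one-sided paired tests,
    one-sided Bayes factors, repeated-measures ANOVA, closed-form and
    simulation-based power analysis). A pipeline driver runs the full
    replication on a synthetic cohort with exclusion screening and
    deterministic seeding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
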