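Package: admixscan
Title: Admixture Mapping and Ancestry-Aware Association for Two-Way Admixed Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for case-control genetic studies of two-way admixed
    populations genotyped on ancestry-informative marker (AIM) panels.
    Implements maximum-likelihood estimation of individual global ancestry,
    a hidden Markov model for per-locus ancestry posteriors, an
    admixture-mapping LOD scan averaged over ancestry risk-ratio disease
    models, risk-ratio exclusion mapping with likelihood-ratio confidence
    intervals, covariate-adjusted single-marker logistic association with
    socioeconomic confounding diagnostics, exact binomial sign tests on
    odds-ratio direction, analytic power, and a synthetic-cohort generator
    that emulates the ancestry, socioeconomic and disease structure such
    studies assume, so every stage is testable without deposited genotypes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
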