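Package: neurocog
Title: Normative Scoring and Multi-Domain Impairment Profiling for
    Neuropsychological Test Batteries
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing comprehensive neuropsychological test
    batteries in clinical cohorts. Raw test scores are converted to T scores
    against user-supplied normative references, transformed to percentiles,
    and labelled with the seven consensus performance bands of the American
    Academy of Clinical Neuropsychology (and their three-category collapse).
    Cognitive domains are derived from the battery by principal component
    analysis with direct-oblimin rotation, loading-threshold assignment and
    explicit reassignment rules, or taken from a built-in 33-score,
    seven-domain default map. Per-patient multi-domain impairment profiles
    are produced by a rule-based classifier over band frequencies, together
    with cohort-level distribution tables, single- versus multi-domain
    summaries, composite T scores, and clinical-correlate analyses
    (correlations, ANCOVA group comparisons, binned chi-square tests).
    A seeded latent-factor cohort simulator with planted domain impairments
    supports end-to-end validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
biocViews: Software, StatisticalMethod, Classification
RoxygenNote: 7.3.3
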