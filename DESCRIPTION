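Package: mltcseq
Title: Clustering Multiple Long-Term Conditions from Longitudinal EHR Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering clusters of people with
    multiple long-term conditions from coded electronic health record
    histories. Generates synthetic primary-care cohorts with known archetype
    structure, builds chronological token sequences with paired age, calendar
    year, gender and visit channels, trains a covariate-aware
    disentangled-attention encoder by replaced-token-detection pretraining
    followed by contrastive fine-tuning, and clusters the resulting patient
    embeddings per gender with bootstrapped cluster-number selection,
    Hungarian-matched centroid stability checks and temporal cohesion
    validation. Clusters are characterised with cluster-weighted disease
    frequencies (c-DF-IPF), one-vs-all association tests, observed/expected
    ratios and exclusivity, with a latent class analysis baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    cluster,
    clue,
    jsonlite,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
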