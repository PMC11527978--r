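Package: sleepclust
Title: Unsupervised Sleep Phenotyping from Nightly Bed-Sensor Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pipeline for unsupervised phenotyping of nightly sleep and
    nocturnal physiology summaries from under-mattress sensors. Converts
    participant-night records (NREM, REM, light and WASO durations plus
    min/avg/max heart and respiratory rate) into per-participant 30-day
    median window samples under missingness exclusion and rolling-mean
    imputation rules, draws age-matched general-population folds, compares
    k-means, Gaussian mixture and Ward agglomerative clusterings over a
    sweep of cluster counts using Silhouette, Calinski-Harabasz and
    Davies-Bouldin indices with bootstrap confidence intervals, harmonizes
    cluster labels across folds by centroid-origin distance, and profiles
    clusters demographically with ANOVA, Tukey post-hoc, t-tests and a
    mixed two-way repeated-measures ANOVA. Includes a seeded synthetic
    cohort generator with planted phenotypes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    mclust,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    cluster,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
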