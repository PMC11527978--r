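---
title: "Methods: unsupervised sleep phenotyping from nightly bed-sensor records"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: unsupervised sleep phenotyping from nightly bed-sensor records}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`sleepclust` implements an unsupervised pipeline for discovering sleep
phenotypes in nightly summaries from under-mattress pressure sensors, and for
asking whether a clinical cohort — people living with dementia (PLWD) —
concentrates in particular phenotypes relative to the general population
(GP). This vignette documents the model, its assumptions, the tunable
parameters, and the design decisions taken where the method left choices
open. It states no empirical result beyond what the package's test suite and
`scripts/acceptance.R` themselves compute.

## 1. Data model and preprocessing

A *night record* is one participant-night with ten features: NREM, REM,
light-sleep and WASO (wake after sleep onset) durations in seconds, and
min/avg/max nocturnal heart rate (beats/min) and respiratory rate
(breaths/min). Nights can be missing wholesale (sensor removed, integration
gaps); partial nights are not modelled.

Preprocessing (`preprocess_nights()`) follows a fixed order: window
extraction → missingness filter → imputation → window medians. Winsorisation
and scaling happen later, per analysis fold.

* **Windows.** The analysis span is `n_windows = 4` consecutive windows of
  `window_len = 30` nights — 120 nights per participant. Windows are
  half-open date intervals anchored, by default, at each participant's first
  recorded night. The anchoring is a deliberate choice: the study design
  fixes calendar spans per cohort, but for synthetic or pooled data a
  per-participant anchor preserves the contiguous four-window structure
  without coupling the analysis to calendar dates. A calendar anchor is
  available via `analysis_start_date`.
* **Exclusion.** A participant is excluded when any window has at least
  `ceiling(missing_threshold * window_len)` missing nights. The threshold is
  expressed with a ceiling so that the default 40 % of a 30-night window
  reproduces an integer cutoff of 12 nights exactly.
* **Imputation.** Remaining gaps are filled with a centered rolling mean
  over `rolling_window = 7` nights, truncated at the series edges, using
  observed values only (so the operation is idempotent). The method
  prescribes a rolling mean without a width; 7 nights balances respecting
  weekly structure against variance of the local estimate. If a gap is wider
  than the rolling window, the participant's mean over that window's
  observed nights substitutes.
* **Medians.** The clustering unit — a *window sample* — is the per-feature
  median over a window's 30 nights. Medians make the unit robust to single
  aberrant nights; with 50 retained clinical participants the design yields
  exactly 200 clinical window samples.

## 2. Age-matched fold construction

The general-population pool is far larger than the clinical cohort, so each
analysis fold pairs all clinical window samples with a random GP subsample of
equal participant count (default 50), drawn *without replacement and
disjointly across the 5 folds*, with per-age-bin quotas proportional to the
clinical cohort's age histogram (5-year bins over 60–98; largest-remainder
rounding so quotas sum exactly). Matching is age-only by design — no
propensity or multivariate matching. Two open points were resolved as
follows: matching is enforced per fold (not merely over the union of folds),
and when a bin's remaining pool cannot fill its quota the deficit is borrowed
from the nearest age bins and logged, because a hard error would make the
legitimate boundary case — a pool exactly the size of the folds with a
slightly different age profile — unusable. `strict = TRUE` restores the hard
error. A with-replacement bootstrap mode exists behind `replace = TRUE` for
designs that need it.

Each fold's combined matrix (default 400 rows × 10 features, 100 unique
participants) is winsorised at the 5th/95th percentiles — limits the method
leaves unstated; these are the conventional choice and are config-exposed —
and z-scaled to zero mean and unit population SD per column. Both statistics
are fit on the combined fold, not per cohort, so cohort differences remain
visible to the clustering.

## 3. Model selection and validity indices

Three clustering families are compared: k-means (centroid-based; k-means++
seeding, Lloyd iterations, 10 restarts, best inertia kept), a Gaussian
mixture model (distribution-based; full covariance, EM via mclust with a
conjugate prior regularizing covariances), and Ward agglomerative clustering
(hierarchical; `ward.D2` on Euclidean distances). For every algorithm and
every k in the sweep range, three internal validity indices are computed,
none requiring ground-truth labels:

* **Silhouette Coefficient** — per point, `(b − a) / max(a, b)`, averaged;
  points in singleton clusters score 0.
* **Calinski–Harabasz** — between/within dispersion ratio on
  `(k − 1, n − k)` degrees of freedom; zero within-scatter returns `Inf`.
* **Davies–Bouldin** — mean worst-pair scatter-to-separation ratio; lower is
  better; coincident centroids are flagged as degenerate rather than
  silently returning a value.

Each (algorithm, k) cell is additionally refit on 15 bootstrap row-resamples,
and the indices are evaluated **on the resample** (the alternative —
evaluating on the full data — was left open by the method; resample
evaluation measures the stability of the fitted structure rather than of the
assignment only). Confidence intervals are percentile 95 % intervals, the
method having specified intervals without a formula. The selection rule ranks
by silhouette, breaking ties by Calinski–Harabasz, then Davies–Bouldin, then
table order (k-means first); ranking uses the full-data point values, with
the bootstrap columns serving as stability diagnostics, and the full ranked
table is returned for audit.

GMM and agglomerative centroids are defined as member means so that label
harmonization treats all algorithms identically.

## 4. Label harmonization across folds

Cluster labels from independent fold fits are arbitrary. They are aligned by
computing each centroid's Euclidean distance from the origin of the scaled
feature space and relabelling `1..k` in ascending order of that distance
(ties broken deterministically by centroid coordinates, with a message). The
direction of "ascending" was ambiguous in the source design; label 1 =
nearest-to-origin is the default and `decreasing = TRUE` inverts it. Note
the caveat this inherits: the origin of the scaled space is the grand mean
of the combined fold, so harmonization is only well defined when the true
cluster centroids sit at distinct distances from that mean. The synthetic
generator's default phenotypes are constructed to satisfy this (Section 6);
real data may not, in which case harmonization should be checked against the
returned centroid norms.

## 5. Profiling and statistics

Per fold and harmonized cluster, the profile records cohort percentages, sex
percentages and mean age over the cluster's *window-sample rows*, then
aggregates each quantity across folds as mean ± SEM, with SEM = sample SD
(n − 1 denominator) of the fold values divided by √(number of folds
contributing); a cluster absent from a fold contributes nothing and the
denominator adjusts. Feature differences between clusters are tested per
feature with one-way ANOVA and Tukey's HSD (Tukey–Kramer for unequal sizes;
adjustment within each feature's pairwise family only — no cross-feature
correction, as none is part of the design), plus pooled-variance independent
t-tests (Welch optional). A two-way mixed ANOVA — cluster as the
between-subject factor, sleep metric as the within-subject factor, window
samples as subjects — partitions the classical sums of squares via an
`Error(subject)` stratum; with a single within level it collapses to the
one-way ANOVA, a property the test suite checks. Degenerate inputs
(all-equal values) return F = 0, p = 1 rather than NaN. An MMSE-by-cluster
comparison for the clinical cohort reuses the one-way ANOVA on participants'
modal cluster assignments.

## 6. The synthetic cohort generator

No raw study data are distributable, so `simulate_sleep_cohort()` generates
cohorts with the statistical structure the pipeline assumes: participant →
phenotype → personal mean → nights.

* **Hierarchy.** Each phenotype has a nightly mean vector; a participant
  draws a personal mean (phenotype mean + between-participant Gaussian
  noise) and each night adds within-participant Gaussian noise, independent
  across nights by default (`ar1_rho` exposes an AR(1) option, off by
  default, since the method states no noise model and independence is the
  simplest assumption the pipeline's medians tolerate). Min/avg/max triplets
  are repaired to preserve ordering; durations truncate at zero.
  Within-night correlations between features are not modelled: features are
  conditionally independent given the phenotype.
* **Demographics.** Three default phenotypes carry mean ages 77.96, 73.53
  and 71.86 years (SD 6.6, truncated to 60–98), conditional PLWD
  probabilities 0.72, 0.46 and 0.34, and female probabilities 0.41, 0.19 and
  0.16, mirroring the published cluster profiles; combined-population shares
  are 28.5/39.1/32.4 %. `phenotype_cohort_weights()` converts these
  share/probability pairs into the per-cohort mixture weights the sampler
  uses. MMSE scores are drawn for PLWD only, from diagnosis-band means
  (Alzheimer's 13.32 ± 5.92 at 55 % of the cohort, vascular 21.83 ± 3.54,
  mixed 7.00 ± 7.55, MCI 25.75 ± 5.97, frontotemporal 29.00, other
  27.50 ± 1.73); GP participants have none.
* **Cohort sizes.** Defaults are 60 PLWD and 300 GP with one sixth of each
  cohort forced above the missingness-exclusion threshold, emulating the
  study's attrition so that 50 PLWD and 250 GP (five disjoint folds of 50)
  survive filtering. Whole-night missingness is MCAR with per-participant
  rates drawn from 5–10 %; the upper rate is kept at 10 % because at
  appreciably higher rates a 30-night window crosses the 12-night exclusion
  cutoff by chance and the designed fold arithmetic breaks.
* **Phenotype geometry.** The planted signatures keep the qualitative
  pattern the pipeline is meant to detect — phenotype 1 (disturbed sleep):
  +light, +WASO, −REM, −NREM, all vitals high, each one between-SD;
  phenotype 2 (consolidated sleep): +NREM, +REM, −WASO, −light at one
  between-SD with moderately low vitals; phenotype 3 (fragmented short
  sleep): all durations markedly short with the lowest vitals. The exact
  magnitudes (phenotype 2 vitals −1.4 SD; phenotype 3 −3.2 SD durations,
  −1.6 SD vitals; WASO between-SD 600 s; phenotypes 2–3 at 0.6 × the
  between-participant spread) were fixed by a design study with two
  requirements that a naive ±1-SD-everywhere layout fails: after
  combined-fold z-scaling the silhouette criterion must genuinely peak at
  three clusters (near-equidistant centroids make a two-cluster merge score
  higher), and the three centroids must sit at distinct distances from the
  grand mean or the centroid-origin harmonization of Section 4 is ill-posed
  on the generator's own output. The final geometry places every pair of
  phenotype means at least 10 within-SD Mahalanobis units apart. What
  passing tests on this generator do **not** show: robustness to weaker or
  anisotropic cluster structure, feature correlations, circadian/seasonal
  trends, or informative (non-MCAR) missingness — none of which the
  generator emulates.

## 7. Numerical and reproducibility choices

* One global seed derives per-stage seeds by hashing `seed/stage`, so any
  stage can be rerun in isolation with an identical stream; identical
  configuration and seed reproduce every output file byte-for-byte
  (`run_pipeline()` writes md5 digests into its manifest; wall-clock
  timings go to a separate file so the manifest itself stays deterministic).
* k-means uses Lloyd iterations with tolerance via `iter.max = 100` and 10
  k-means++ restarts; the GMM regularizes covariances with mclust's
  conjugate prior instead of failing on near-singular fits; bootstrap
  resamples that produce an empty cluster or an undefined index are redrawn
  up to 10 times.
* Quantile operations (winsorisation, bootstrap CIs) use R's default type-7
  quantiles; z-scaling uses the population (divisor-n) SD; constant columns
  scale to zeros with a warning rather than NaN.
* Problem sizes in the test suite are the study's own: 360 simulated
  participants × 120 nights, 5 folds of 400 × 10 matrices, a 3-algorithm ×
  k ∈ [2, 10] sweep with 15 bootstrap refits — chosen because the full
  design is small enough to run end-to-end in well under a minute, so there
  is no reason to test a reduced surrogate.

## 8. Known limitations

* The pipeline clusters window samples, not participants; a participant's
  four windows may land in different clusters, and profiles are row-level.
  Participant-level statements (e.g. the MMSE comparison) use modal
  assignments.
* Harmonization by centroid-origin distance is a heuristic; it fails when
  two true centroids are near-equidistant from the grand mean (Section 4).
* Internal validity indices reward compact spherical structure; a selection
  by silhouette can prefer merging genuinely distinct but adjacent
  phenotypes. The full audit table is returned so alternative rules can be
  applied.
* The statistical comparisons treat window samples as independent
  observations within a fold, as the source design does; the two-way mixed
  ANOVA is the only place the repeated-measures structure enters.
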