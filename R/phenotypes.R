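#' Define a planted sleep phenotype
#'
#' A phenotype is a participant-level archetype of nightly sleep architecture
#' and nocturnal vitals. Participants of a phenotype get a personal mean vector
#' drawn around `nightly_mean` with `between_participant_sd`, and each of their
#' nights scatters around the personal mean with `within_participant_sd`.
#'
#' @param phenotype_id Integer label (>= 1).
#' @param nightly_mean Named numeric 10-vector in [sleep_features()] order:
#'   durations in seconds, heart rate in beats/min, respiratory rate in
#'   breaths/min. Must satisfy `hr_min <= hr_avg <= hr_max` and likewise for
#'   respiratory rate; durations must be non-negative.
#' @param between_participant_sd Non-negative 10-vector of participant-level SDs.
#' @param within_participant_sd Non-negative 10-vector of night-level noise SDs.
#' @param age_mean,age_sd Age distribution (years) for the phenotype; ages are
#'   drawn from this normal law truncated to the configured cohort range.
#' @param prob_plwd Probability that a participant of this phenotype belongs to
#'   the PLWD (people living with dementia) cohort; used to derive the default
#'   per-cohort phenotype weights.
#' @param prob_female Probability of sex `"F"`.
#' @return An object of class `phenotype_spec`.
#' @export
#' @examples
#' str(default_phenotypes()[[1]])
phenotype_spec <- function(phenotype_id, nightly_mean, between_participant_sd,
                           within_participant_sd, age_mean, age_sd,
                           prob_plwd, prob_female) {
  feats <- sleep_features()
  nm <- function(v, what) {
    if (is.null(names(v))) names(v) <- feats
    v <- v[feats]
    if (length(v) != 10L || any(is.na(v)))
      stop(sprintf("%s must be a 10-vector over %s", what,
                   paste(feats, collapse = ", ")), call. = FALSE)
    v
  }
  nightly_mean <- nm(nightly_mean, "nightly_mean")
  between_participant_sd <- nm(between_participant_sd, "between_participant_sd")
  within_participant_sd <- nm(within_participant_sd, "within_participant_sd")
  if (any(between_participant_sd < 0) || any(within_participant_sd < 0))
    stop("SDs must be non-negative", call. = FALSE)
  if (age_sd < 0) stop("age_sd must be non-negative", call. = FALSE)
  .assert_prob(prob_plwd, "prob_plwd")
  .assert_prob(prob_female, "prob_female")
  if (any(nightly_mean[.duration_features()] < 0))
    stop("duration means must be non-negative", call. = FALSE)
  if (nightly_mean["hr_min"] > nightly_mean["hr_avg"] ||
      nightly_mean["hr_avg"] > nightly_mean["hr_max"])
    stop("nightly_mean must satisfy hr_min <= hr_avg <= hr_max", call. = FALSE)
  if (nightly_mean["rr_min"] > nightly_mean["rr_avg"] ||
      nightly_mean["rr_avg"] > nightly_mean["rr_max"])
    stop("nightly_mean must satisfy rr_min <= rr_avg <= rr_max", call. = FALSE)
  structure(list(phenotype_id = as.integer(phenotype_id),
                 nightly_mean = nightly_mean,
                 between_participant_sd = between_participant_sd,
                 within_participant_sd = within_participant_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 prob_plwd = prob_plwd, prob_female = prob_female),
            class = "phenotype_spec")
}

# baseline elderly nightly sleep architecture and vitals; shifts below are in
# units of the between-participant SD
.base_night <- function() {
  c(nrem_s = 4500, rem_s = 5400, light_s = 12600, waso_s = 2700,
    hr_min = 52, hr_avg = 60, hr_max = 75,
    rr_min = 12, rr_avg = 14.5, rr_max = 17.5)
}

.between_sd <- function() {
  c(nrem_s = 900, rem_s = 1080, light_s = 1800, waso_s = 600,
    hr_min = 6, hr_avg = 6, hr_max = 7,
    rr_min = 1.2, rr_avg = 1.2, rr_max = 1.5)
}

#' Default planted phenotypes
#'
#' Three phenotypes encoding the qualitative cluster signatures the pipeline is
#' designed to detect:
#' \describe{
#'   \item{1 — disturbed sleep}{one between-SD more light sleep and WASO, one
#'     less REM/NREM, and heart and respiratory rates one between-SD high;
#'     oldest (mean age 77.96); mostly PLWD (72\%) and majority female. The
#'     clinically heterogeneous phenotype: full between-participant spread.}
#'   \item{2 — consolidated sleep}{one between-SD more NREM and REM, one less
#'     WASO and light sleep; vitals moderately low but above phenotype 3's;
#'     mixed cohort (46\% PLWD); homogeneous (0.6 x between-SD spread).}
#'   \item{3 — fragmented short sleep}{markedly short durations across the
#'     board with the lowest nocturnal vitals; youngest and mostly general
#'     population (34\% PLWD); homogeneous (0.6 x between-SD spread).}
#' }
#' The geometry is deliberately scalene: every pair of phenotype means is at
#' least 10 apart in within-SD Mahalanobis units (night-level noise), the
#' minimum scaled-space inter-centroid distance is large enough that the
#' silhouette criterion peaks at three clusters, and the three centroids sit
#' at distinct distances from the population grand mean so that
#' centroid-origin label harmonization is well defined across resampled
#' folds.
#'
#' @param separation Multiplier on the signature shifts (1 = default planted
#'   effect size; larger values make phenotypes easier to recover).
#' @return List of three [phenotype_spec()] objects.
#' @export
default_phenotypes <- function(separation = 1) {
  base <- .base_night()
  bsd <- .between_sd()
  wsd <- bsd / 1.5
  shift <- function(s) base + separation * s * bsd
  sig1 <- c(nrem_s = -1, rem_s = -1, light_s = 1, waso_s = 1,
            hr_min = 1, hr_avg = 1, hr_max = 1,
            rr_min = 1, rr_avg = 1, rr_max = 1)
  sig2 <- c(nrem_s = 1, rem_s = 1, light_s = -1, waso_s = -1,
            hr_min = -1.4, hr_avg = -1.4, hr_max = -1.4,
            rr_min = -1.4, rr_avg = -1.4, rr_max = -1.4)
  sig3 <- c(nrem_s = -3.2, rem_s = -3.2, light_s = -3.2, waso_s = -3.2,
            hr_min = -1.6, hr_avg = -1.6, hr_max = -1.6,
            rr_min = -1.6, rr_avg = -1.6, rr_max = -1.6)
  list(
    phenotype_spec(1L, shift(sig1), bsd, wsd, age_mean = 77.96, age_sd = 6.6,
                   prob_plwd = 0.72, prob_female = 0.41),
    phenotype_spec(2L, shift(sig2), 0.6 * bsd, wsd, age_mean = 73.53,
                   age_sd = 6.6, prob_plwd = 0.46, prob_female = 0.19),
    phenotype_spec(3L, shift(sig3), 0.6 * bsd, wsd, age_mean = 71.86,
                   age_sd = 6.6, prob_plwd = 0.34, prob_female = 0.16)
  )
}

#' Per-cohort phenotype weights from shares and PLWD fractions
#'
#' Converts a marginal phenotype share vector (fraction of the combined
#' PLWD+GP population in each phenotype) and each phenotype's conditional
#' PLWD probability into the per-cohort sampling weights
#' [sample_participants()] consumes, assuming the two cohorts contribute
#' equally to the combined population (as in an equal-n fold).
#'
#' @param shares Combined-population phenotype shares (sums to 1 after
#'   normalization).
#' @param prob_plwd Per-phenotype probability of PLWD membership.
#' @return List with unit-sum numeric vectors `plwd` and `gp`.
#' @export
#' @examples
#' phenotype_cohort_weights(c(0.285, 0.391, 0.324), c(0.72, 0.46, 0.34))
phenotype_cohort_weights <- function(shares, prob_plwd) {
  stopifnot(length(shares) == length(prob_plwd))
  .assert_prob(prob_plwd, "prob_plwd")
  shares <- shares / sum(shares)
  plwd <- shares * prob_plwd
  gp <- shares * (1 - prob_plwd)
  list(plwd = plwd / sum(plwd), gp = gp / sum(gp))
}
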