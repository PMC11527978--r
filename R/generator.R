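#' Synthetic cohort generator configuration
#'
#' Defaults emulate the study design the pipeline targets: a clinical PLWD
#' cohort whose attrition under the 40\% missingness filter leaves 50
#' participants, and a general-population pool leaving 250 (five folds of 50),
#' each observed for 120 consecutive nights.
#'
#' @param n_plwd Number of PLWD-cohort participants (default 60; with
#'   `frac_excludable = 1/6`, 50 survive the downstream missingness filter).
#' @param n_gp_pool Number of general-population pool participants (default
#'   300, leaving 250 after exclusion).
#' @param n_nights Consecutive nights per participant (default 120).
#' @param start_date First night date.
#' @param phenotype_weights List with unit-sum numeric vectors `plwd` and `gp`
#'   giving each cohort's phenotype mixture; default derives from the planted
#'   phenotype shares (28.5/39.1/32.4\%) and conditional PLWD fractions
#'   (72/46/34\%) via [phenotype_cohort_weights()].
#' @param missing_night_prob_range Interval from which each participant's
#'   whole-night missingness probability is drawn uniformly.
#' @param frac_excludable Fraction of each cohort forced above the downstream
#'   missingness-exclusion threshold (>= 12 missing nights in a 30-night
#'   window).
#' @param age_range Truncation range for sampled ages, years.
#' @param ar1_rho Lag-1 autocorrelation of the nightly noise; 0 (default)
#'   gives independent nights.
#' @param seed Integer seed; identical seeds give byte-identical cohorts.
#' @return An object of class `generator_config` (a validated list).
#' @export
generator_config <- function(n_plwd = 60L, n_gp_pool = 300L, n_nights = 120L,
                             start_date = as.Date("2022-10-31"),
                             phenotype_weights = phenotype_cohort_weights(
                               c(0.285, 0.391, 0.324), c(0.72, 0.46, 0.34)),
                             missing_night_prob_range = c(0.05, 0.10),
                             frac_excludable = 1 / 6,
                             age_range = c(60, 98),
                             ar1_rho = 0,
                             seed = 1L) {
  stopifnot(n_plwd >= 0, n_gp_pool >= 0, n_nights >= 1,
            length(missing_night_prob_range) == 2L,
            diff(missing_night_prob_range) >= 0,
            length(age_range) == 2L, age_range[1] < age_range[2],
            abs(ar1_rho) < 1)
  .assert_prob(missing_night_prob_range, "missing_night_prob_range")
  .assert_prob(frac_excludable, "frac_excludable")
  if (!is.list(phenotype_weights) ||
      !all(c("plwd", "gp") %in% names(phenotype_weights)))
    stop("phenotype_weights must be a list with elements 'plwd' and 'gp'",
         call. = FALSE)
  structure(list(n_plwd = as.integer(n_plwd),
                 n_gp_pool = as.integer(n_gp_pool),
                 n_nights = as.integer(n_nights),
                 start_date = as.Date(start_date),
                 phenotype_weights = phenotype_weights,
                 missing_night_prob_range = missing_night_prob_range,
                 frac_excludable = frac_excludable,
                 age_range = age_range,
                 ar1_rho = ar1_rho,
                 seed = as.integer(seed)),
            class = "generator_config")
}

# truncated-normal draw via inverse CDF so it stays deterministic and exact
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (n == 0L) return(numeric(0))
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

# MMSE diagnosis bands for the PLWD cohort: share of cohort, band mean and SD
.mmse_bands <- function() {
  data.frame(
    diagnosis = c("alzheimers", "vascular", "mixed", "mci",
                  "frontotemporal", "other"),
    share = c(0.55, 0.15, 0.075, 0.10, 0.025, 0.10),
    mean = c(13.32, 21.83, 7.00, 25.75, 29.00, 27.50),
    sd = c(5.92, 3.54, 7.55, 5.97, 0.00, 1.73)
  )
}

#' Sample synthetic participants
#'
#' Draws the participant table: cohort, phenotype (from cohort-specific
#' mixture weights), age (phenotype normal law truncated to the configured
#' range), sex, and — for PLWD only — an MMSE score sampled from
#' diagnosis-band means.
#'
#' @param config A [generator_config()].
#' @param specs Non-empty list of [phenotype_spec()] objects.
#' @return `data.frame` with columns `participant_id`, `cohort` (`"PLWD"` /
#'   `"GP"`), `age`, `sex`, `mmse` (NA for GP), `true_phenotype`. The
#'   `true_phenotype` column exists for evaluation only; no pipeline stage
#'   reads it.
#' @export
sample_participants <- function(config, specs) {
  if (!length(specs)) stop("specs must be non-empty", call. = FALSE)
  w <- config$phenotype_weights
  for (cw in w[c("plwd", "gp")]) {
    if (length(cw) != length(specs) || any(cw < 0) || sum(cw) <= 0)
      stop("phenotype weights must be non-negative, match specs in length, and have positive sum",
           call. = FALSE)
  }
  set.seed(derive_seed(config$seed, "participants"))
  one_cohort <- function(n, cohort, weights, prefix) {
    if (n == 0L) return(NULL)
    weights <- weights / sum(weights)
    ph <- sample.int(length(specs), n, replace = TRUE, prob = weights)
    age_mean <- vapply(specs, `[[`, numeric(1), "age_mean")[ph]
    age_sd <- vapply(specs, `[[`, numeric(1), "age_sd")[ph]
    age <- .rtruncnorm(n, age_mean, age_sd,
                       config$age_range[1], config$age_range[2])
    pf <- vapply(specs, `[[`, numeric(1), "prob_female")[ph]
    sex <- ifelse(stats::runif(n) < pf, "F", "M")
    mmse <- rep(NA_integer_, n)
    if (cohort == "PLWD") {
      bands <- .mmse_bands()
      b <- sample.int(nrow(bands), n, replace = TRUE, prob = bands$share)
      mmse <- as.integer(pmin(30, pmax(0, round(
        stats::rnorm(n, bands$mean[b], bands$sd[b])))))
    }
    data.frame(participant_id = sprintf("%s%04d", prefix, seq_len(n)),
               cohort = cohort, age = age, sex = sex, mmse = mmse,
               true_phenotype = vapply(specs, `[[`, integer(1),
                                       "phenotype_id")[ph],
               stringsAsFactors = FALSE)
  }
  out <- rbind(one_cohort(config$n_plwd, "PLWD", w$plwd, "P"),
               one_cohort(config$n_gp_pool, "GP", w$gp, "G"))
  if (is.null(out))
    out <- data.frame(participant_id = character(0), cohort = character(0),
                      age = numeric(0), sex = character(0),
                      mmse = integer(0), true_phenotype = integer(0))
  rownames(out) <- NULL
  out
}

# enforce min <= avg <= max on a (n x 3) block: min = avg - |min_raw - avg|,
# max = avg + |max_raw - avg|
.repair_triplet <- function(m) {
  avg <- m[, 2L]
  cbind(avg - abs(m[, 1L] - avg), avg, avg + abs(m[, 3L] - avg))
}

#' Simulate complete nightly records
#'
#' Each participant receives a personal mean vector (phenotype mean plus
#' between-participant Gaussian noise); each night adds within-participant
#' noise (optionally AR(1) across nights). Heart- and respiratory-rate
#' triplets are repaired to preserve min <= avg <= max, and durations are
#' truncated at zero. Every participant gets exactly `n_nights` consecutive
#' dates starting at `start_date`.
#'
#' @param participants Output of [sample_participants()].
#' @param specs The same phenotype list used to sample participants.
#' @param config A [generator_config()].
#' @return `data.frame` with `participant_id`, `night_date` and the ten
#'   feature columns of [sleep_features()], one row per participant-night.
#' @export
simulate_nights <- function(participants, specs, config) {
  ids <- vapply(specs, `[[`, integer(1), "phenotype_id")
  if (!all(participants$true_phenotype %in% ids))
    stop("every participant's phenotype needs a spec", call. = FALSE)
  set.seed(derive_seed(config$seed, "nights"))
  feats <- sleep_features()
  n_nights <- config$n_nights
  dates <- config$start_date + seq_len(n_nights) - 1L
  rho <- config$ar1_rho
  blocks <- vector("list", nrow(participants))
  for (i in seq_len(nrow(participants))) {
    spec <- specs[[match(participants$true_phenotype[i], ids)]]
    personal <- spec$nightly_mean +
      stats::rnorm(10L) * spec$between_participant_sd
    eps <- matrix(stats::rnorm(n_nights * 10L), n_nights, 10L)
    if (rho != 0) { # stationary AR(1) with unit marginal variance
      for (t in 2:n_nights)
        eps[t, ] <- rho * eps[t - 1L, ] + sqrt(1 - rho^2) * eps[t, ]
    }
    x <- sweep(eps, 2L, spec$within_participant_sd, `*`)
    x <- sweep(x, 2L, personal, `+`)
    colnames(x) <- feats
    x[, 5:7] <- .repair_triplet(x[, 5:7, drop = FALSE])
    x[, 8:10] <- .repair_triplet(x[, 8:10, drop = FALSE])
    x[, .duration_features()] <- pmax(x[, .duration_features()], 0)
    blocks[[i]] <- data.frame(
      participant_id = participants$participant_id[i],
      night_date = dates, x, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(blocks, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- cbind(data.frame(participant_id = character(0),
                            night_date = as.Date(character(0))),
                 stats::setNames(as.data.frame(matrix(numeric(0), 0, 10)),
                                 feats))
  out
}

#' Inject whole-night missingness
#'
#' Each participant gets a missing-night probability drawn uniformly from the
#' configured range; nights are then blanked independently (MCAR at the night
#' level). A `frac_excludable` subset of each cohort additionally has the
#' first `ceil(0.4 * 30) = 12` nights forced missing, guaranteeing exclusion
#' by the default downstream filter. Rows are retained with all ten features
#' set to `NA`, so the record count is unchanged.
#'
#' @param records Complete nights from [simulate_nights()].
#' @param participants The participant table.
#' @param config A [generator_config()].
#' @return `records` with missing nights blanked.
#' @export
inject_missingness <- function(records, participants, config) {
  if (anyNA(records[, sleep_features()]))
    stop("records must be complete before missingness injection", call. = FALSE)
  set.seed(derive_seed(config$seed, "missingness"))
  lo <- config$missing_night_prob_range[1]
  hi <- config$missing_night_prob_range[2]
  rate <- stats::setNames(stats::runif(nrow(participants), lo, hi),
                          participants$participant_id)
  force_ids <- character(0)
  for (ch in unique(participants$cohort)) {
    ids <- participants$participant_id[participants$cohort == ch]
    n_force <- round(config$frac_excludable * length(ids))
    if (n_force > 0)
      force_ids <- c(force_ids, sample(ids, n_force))
  }
  n_force_nights <- ceiling(0.4 * 30) # default filter geometry: 12 of 30
  miss <- stats::runif(nrow(records)) < rate[records$participant_id]
  if (length(force_ids)) {
    first <- stats::ave(seq_len(nrow(records)), records$participant_id,
                        FUN = seq_along)
    miss <- miss | (records$participant_id %in% force_ids &
                      first <= n_force_nights)
  }
  records[miss, sleep_features()] <- NA_real_
  records
}

#' Simulate a full synthetic sleep cohort
#'
#' Convenience wrapper chaining [sample_participants()], [simulate_nights()]
#' and [inject_missingness()].
#'
#' @param config A [generator_config()].
#' @param specs List of [phenotype_spec()]; defaults to [default_phenotypes()].
#' @return List of class `sleep_cohort` with elements `participants`,
#'   `nights` and `config`.
#' @export
#' @examples
#' co <- simulate_sleep_cohort(generator_config(n_plwd = 4, n_gp_pool = 4,
#'                                              n_nights = 40, seed = 7))
#' table(co$participants$cohort)
simulate_sleep_cohort <- function(config = generator_config(),
                                  specs = default_phenotypes()) {
  participants <- sample_participants(config, specs)
  nights <- simulate_nights(participants, specs, config)
  nights <- inject_missingness(nights, participants, config)
  structure(list(participants = participants, nights = nights,
                 config = config), class = "sleep_cohort")
}

#' Write a synthetic cohort to CSV
#'
#' Writes `participants.csv`, `nights.csv` (ISO-8601 dates; missing nights as
#' empty fields) and a `cohort_meta.json` sidecar recording the configuration
#' and seed.
#'
#' @param cohort A `sleep_cohort` from [simulate_sleep_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sleep_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pp <- file.path(dir, "participants.csv")
  np <- file.path(dir, "nights.csv")
  mp <- file.path(dir, "cohort_meta.json")
  utils::write.csv(cohort$participants, pp, row.names = FALSE, na = "")
  nights <- cohort$nights
  nights$night_date <- format(nights$night_date, "%Y-%m-%d")
  utils::write.csv(nights, np, row.names = FALSE, na = "")
  cfg <- cohort$config
  cfg$start_date <- format(cfg$start_date, "%Y-%m-%d")
  jsonlite::write_json(unclass(cfg), mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(participants = pp, nights = np, meta = mp))
}

#' Read a cohort written by [write_sleep_cohort()]
#'
#' @param dir Directory holding `participants.csv` and `nights.csv`.
#' @return List with `participants` and `nights` data frames.
#' @export
read_sleep_cohort <- function(dir) {
  participants <- utils::read.csv(file.path(dir, "participants.csv"),
                                  stringsAsFactors = FALSE)
  nights <- utils::read.csv(file.path(dir, "nights.csv"),
                            stringsAsFactors = FALSE)
  nights$night_date <- as.Date(nights$night_date)
  list(participants = participants, nights = nights)
}
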