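#' Fold sampling plan
#'
#' Plan for drawing the age-matched, disjoint general-population folds that
#' are each combined with the clinical cohort for clustering.
#'
#' @param n_folds Number of folds (default 5).
#' @param per_fold GP participants per fold (default 50).
#' @param age_bins Bin edges (years) for age matching; default 5-year bins
#'   over 60-98.
#' @param replace Draw folds with replacement (bootstrap mode) instead of the
#'   default disjoint without-replacement sampling.
#' @param seed Integer seed for the draws.
#' @return An object of class `fold_plan`.
#' @export
fold_plan <- function(n_folds = 5L, per_fold = 50L,
                      age_bins = c(seq(60, 95, by = 5), 98),
                      replace = FALSE, seed = 1L) {
  stopifnot(n_folds >= 1, per_fold >= 1, length(age_bins) >= 2,
            !is.unsorted(age_bins, strictly = TRUE))
  structure(list(n_folds = as.integer(n_folds),
                 per_fold = as.integer(per_fold),
                 age_bins = age_bins, replace = isTRUE(replace),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

.bin_ages <- function(age, bins) {
  # left-closed bins [a, b), last bin closed; ages outside the edges fall in
  # the end bins so the bins always cover the cohort range
  cut(pmin(pmax(age, bins[1]), bins[length(bins)]), bins,
      include.lowest = TRUE, right = FALSE)
}

#' Reference age distribution of the clinical cohort
#'
#' @param plwd_participants Participant table rows for the retained PLWD
#'   cohort (needs an `age` column).
#' @param age_bins Bin edges in years.
#' @return Named numeric vector of per-bin proportions summing to 1.
#' @export
build_age_reference <- function(plwd_participants, age_bins) {
  if (!nrow(plwd_participants)) stop("empty cohort", call. = FALSE)
  tab <- table(.bin_ages(plwd_participants$age, age_bins))
  prop <- as.numeric(tab) / sum(tab)
  stats::setNames(prop, names(tab))
}

#' Draw age-matched general-population folds
#'
#' Each fold draws `per_fold` participants from the GP pool with per-age-bin
#' quotas equal to `per_fold` times the reference proportion
#' (largest-remainder rounding, ties broken by bin order), uniformly without
#' replacement within bins; fold sets are disjoint across folds. When a bin's
#' remaining pool cannot fill its quota the deficit is borrowed from the
#' nearest age bins (recorded in the result); with `strict = TRUE` a shortfall
#' is an error naming the bin.
#'
#' @param gp_pool Participant table rows for the GP pool (needs
#'   `participant_id` and `age`).
#' @param reference Per-bin proportions from [build_age_reference()].
#' @param plan A [fold_plan()].
#' @param strict Error on bin shortfall instead of borrowing.
#' @return List of class `fold_assignment`: `folds` (list of participant-id
#'   vectors), `quotas` (bin x fold matrix), `borrowed` (log of bin
#'   substitutions) and the plan.
#' @export
sample_folds <- function(gp_pool, reference, plan, strict = FALSE) {
  need <- plan$n_folds * plan$per_fold
  if (!plan$replace && nrow(gp_pool) < need)
    stop(sprintf("GP pool (%d) smaller than n_folds * per_fold (%d)",
                 nrow(gp_pool), need), call. = FALSE)
  set.seed(derive_seed(plan$seed, "folds"))
  bins <- .bin_ages(gp_pool$age, plan$age_bins)
  bin_levels <- levels(bins)
  if (length(reference) != length(bin_levels))
    stop("reference proportions do not match the plan's age bins",
         call. = FALSE)
  quota <- largest_remainder(reference, plan$per_fold)
  available <- split(gp_pool$participant_id, bins)
  borrowed <- list()
  folds <- vector("list", plan$n_folds)
  for (f in seq_len(plan$n_folds)) {
    take <- character(0)
    deficit <- integer(length(bin_levels))
    for (b in seq_along(bin_levels)) {
      pool_b <- available[[b]]
      n_take <- min(quota[b], length(pool_b))
      if (n_take < quota[b]) {
        if (strict)
          stop(sprintf("insufficient GP pool in age bin %s (need %d, have %d)",
                       bin_levels[b], quota[b], length(pool_b)), call. = FALSE)
        deficit[b] <- quota[b] - n_take
      }
      if (n_take > 0) {
        pick <- if (length(pool_b) == 1L) pool_b else
          sample(pool_b, n_take)
        take <- c(take, pick)
        if (!plan$replace)
          available[[b]] <- setdiff(available[[b]], pick)
      }
    }
    # borrow deficits from the nearest bins that still have supply
    for (b in which(deficit > 0)) {
      order_near <- order(abs(seq_along(bin_levels) - b))
      for (nb in order_near) {
        if (deficit[b] == 0) break
        pool_nb <- setdiff(available[[nb]], take)
        if (!length(pool_nb)) next
        n_take <- min(deficit[b], length(pool_nb))
        pick <- if (length(pool_nb) == 1L) pool_nb else sample(pool_nb, n_take)
        take <- c(take, pick)
        if (!plan$replace)
          available[[nb]] <- setdiff(available[[nb]], pick)
        borrowed[[length(borrowed) + 1L]] <- data.frame(
          fold = f, short_bin = bin_levels[b], from_bin = bin_levels[nb],
          n = n_take, stringsAsFactors = FALSE)
        deficit[b] <- deficit[b] - n_take
      }
      if (deficit[b] > 0)
        stop(sprintf("GP pool exhausted while filling age bin %s in fold %d",
                     bin_levels[b], f), call. = FALSE)
    }
    folds[[f]] <- sort(take)
  }
  structure(list(folds = folds,
                 quotas = matrix(quota, ncol = plan$n_folds,
                                 nrow = length(quota),
                                 dimnames = list(bin_levels, NULL)),
                 borrowed = if (length(borrowed))
                   do.call(rbind, borrowed) else NULL,
                 plan = plan),
            class = "fold_assignment")
}

#' Assemble one combined fold matrix
#'
#' Concatenates the clinical window samples with the fold's GP window
#' samples, then winsorises and z-scales the combined matrix (scaling is fit
#' on the combined fold, not per cohort).
#'
#' @param plwd_samples Window samples (from [preprocess_nights()]) for the
#'   retained PLWD cohort.
#' @param gp_samples Window samples for this fold's GP participants.
#' @param config A [pipeline_config()] (supplies the winsor limits).
#' @param fold_index Integer index recorded on the result.
#' @return List of class `fold_dataset`: `x` (scaled matrix), `meta` (row
#'   metadata: participant, cohort, age, sex, window), `scaling` (the
#'   [zscore()] fit), `fold_index`.
#' @export
assemble_fold <- function(plwd_samples, gp_samples, config = pipeline_config(),
                          fold_index = 0L) {
  feats <- sleep_features()
  .assert_feature_cols(plwd_samples, "PLWD window samples")
  if (nrow(gp_samples)) .assert_feature_cols(gp_samples, "GP window samples")
  common <- intersect(names(plwd_samples), names(gp_samples))
  both <- rbind(plwd_samples[, common, drop = FALSE],
                gp_samples[, common, drop = FALSE])
  raw <- as.matrix(both[, feats])
  w <- winsorise(raw, config$winsor_limits)
  sc <- zscore(w)
  meta <- both[, intersect(c("participant_id", "cohort", "age", "sex",
                             "window_index"), names(both))]
  rownames(meta) <- NULL
  x <- sc$scaled
  rownames(x) <- NULL
  structure(list(x = x, meta = meta, scaling = sc[c("center", "scale")],
                 fold_index = as.integer(fold_index)),
            class = "fold_dataset")
}
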