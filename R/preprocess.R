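#' Preprocessing configuration
#'
#' Windowing, exclusion, imputation and outlier-handling rules for turning
#' nightly records into per-participant 30-day median window samples.
#'
#' @param n_windows Number of consecutive analysis windows (default 4).
#' @param window_len Nights per window (default 30, so the default analysis
#'   span is 120 nights).
#' @param missing_threshold Fraction of a window that may be missing before a
#'   participant is excluded; the exclusion threshold in nights is
#'   `ceiling(missing_threshold * window_len)` — 12 with the defaults.
#' @param rolling_window Width (nights) of the centered, edge-truncated
#'   rolling-mean imputation window (default 7).
#' @param winsor_limits Lower/upper quantiles for winsorisation, default
#'   `c(0.05, 0.95)`.
#' @param analysis_start_date Optional calendar anchor for window 0. When
#'   `NULL` (default) windows are anchored at each participant's first
#'   recorded night, preserving the contiguous-window structure without
#'   calendar coupling.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_windows = 4L, window_len = 30L,
                            missing_threshold = 0.4, rolling_window = 7L,
                            winsor_limits = c(0.05, 0.95),
                            analysis_start_date = NULL) {
  stopifnot(n_windows >= 1, window_len >= 1, rolling_window >= 1,
            missing_threshold > 0, missing_threshold <= 1,
            length(winsor_limits) == 2L,
            winsor_limits[1] >= 0, winsor_limits[2] <= 1,
            winsor_limits[1] < winsor_limits[2])
  structure(list(n_windows = as.integer(n_windows),
                 window_len = as.integer(window_len),
                 missing_threshold = missing_threshold,
                 rolling_window = as.integer(rolling_window),
                 winsor_limits = winsor_limits,
                 analysis_start_date = if (is.null(analysis_start_date)) NULL
                                       else as.Date(analysis_start_date)),
            class = "pipeline_config")
}

#' Assign nights to analysis windows
#'
#' Windows are consecutive, non-overlapping half-open date intervals
#' `[anchor + i * L, anchor + (i + 1) * L)` for `i = 0 .. n_windows - 1`.
#' Nights outside the span are dropped; a night with any missing feature
#' counts as a missing night. Missing-night counts per window include dates
#' with no record at all.
#'
#' @param records Nightly records (`participant_id`, `night_date`, features).
#' @param config A [pipeline_config()].
#' @return List with `nights` (in-span records plus a `window_index` column),
#'   `missing_counts` (participant x window data frame of missing nights) and
#'   `flagged` (participants with zero in-span nights — flagged, not dropped
#'   silently).
#' @export
extract_windows <- function(records, config) {
  .assert_feature_cols(records, "records")
  records$night_date <- as.Date(records$night_date)
  records <- records[order(records$participant_id, records$night_date), ]
  ids <- unique(records$participant_id)
  anchor <- if (is.null(config$analysis_start_date)) {
    tapply(records$night_date, records$participant_id, min)[ids]
  } else {
    stats::setNames(rep(as.numeric(config$analysis_start_date),
                        length(ids)), ids)
  }
  span <- config$n_windows * config$window_len
  off <- as.numeric(records$night_date) - anchor[records$participant_id]
  win <- floor(off / config$window_len)
  keep <- off >= 0 & off < span
  nights <- records[keep, , drop = FALSE]
  nights$window_index <- as.integer(win[keep])
  flagged <- ids[!(ids %in% nights$participant_id)]
  present <- !apply(is.na(nights[, sleep_features(), drop = FALSE]), 1L, any)
  grid <- expand.grid(participant_id = ids,
                      window_index = seq_len(config$n_windows) - 1L,
                      stringsAsFactors = FALSE)
  key <- paste(nights$participant_id[present], nights$window_index[present])
  obs <- table(factor(key, levels = paste(grid$participant_id,
                                          grid$window_index)))
  grid$n_missing <- config$window_len - as.integer(obs)
  list(nights = nights, missing_counts = grid, flagged = flagged)
}

#' Exclude participants by window missingness
#'
#' A participant is excluded iff the missing-night count in any window reaches
#' `ceiling(missing_threshold * window_len)` — 12 or more of 30 with the
#' defaults.
#'
#' @param windows Output of [extract_windows()].
#' @param config A [pipeline_config()].
#' @return List with `retained` (participant ids) and `exclusions` (data frame
#'   of excluded participants with the offending window and its missing count).
#' @export
apply_missingness_filter <- function(windows, config) {
  thr <- ceiling(config$missing_threshold * config$window_len)
  mc <- windows$missing_counts
  worst <- do.call(rbind, lapply(split(mc, mc$participant_id), function(d) {
    i <- which.max(d$n_missing)
    d[i, , drop = FALSE]
  }))
  excluded <- worst[worst$n_missing >= thr, , drop = FALSE]
  retained <- setdiff(unique(mc$participant_id), excluded$participant_id)
  rownames(excluded) <- NULL
  names(excluded)[names(excluded) == "window_index"] <- "offending_window"
  list(retained = retained, exclusions = excluded, threshold_nights = thr)
}

# centered edge-truncated rolling mean of the observed values of x; positions
# with no observed neighbour get NA
.rolling_obs_mean <- function(x, width) {
  n <- length(x)
  h <- floor(width / 2)
  obs <- !is.na(x)
  cs <- cumsum(ifelse(obs, x, 0))
  cn <- cumsum(obs)
  i <- seq_len(n)
  lo <- pmax(i - h, 1L)
  hi <- pmin(i + h, n)
  s <- cs[hi] - c(0, cs)[lo]   # cumulative sum just before the window start
  k <- cn[hi] - c(0, cn)[lo]
  ifelse(k > 0, s / k, NA_real_)
}

#' Impute missing nights with a centered rolling mean
#'
#' Each absent value is replaced by the mean of the observed values within a
#' centered window of `rolling_window` nights (truncated at the series edges),
#' preserving the temporal structure of the data. If the rolling window holds
#' no observed value, the participant's mean over that analysis window's
#' observed nights is used. Observed values are never altered, so the
#' operation is idempotent.
#'
#' @param windows Output of [extract_windows()], restricted to retained
#'   participants if a filter was applied.
#' @param config A [pipeline_config()].
#' @return The `windows` list with `nights` completed (no missing features).
#' @export
impute_rolling_mean <- function(windows, config) {
  nights <- windows$nights
  feats <- sleep_features()
  for (id in unique(nights$participant_id)) {
    rows <- which(nights$participant_id == id)
    rows <- rows[order(nights$night_date[rows])]
    for (f in feats) {
      x <- nights[rows, f]
      if (!anyNA(x)) next
      if (all(is.na(x)))
        stop(sprintf("participant %s has no observed values for %s", id, f),
             call. = FALSE)
      filled <- .rolling_obs_mean(x, config$rolling_window)
      # fallback: mean of observed values within the same analysis window
      if (anyNA(filled)) {
        wmean <- tapply(x, nights$window_index[rows],
                        function(v) mean(v, na.rm = TRUE))
        filled[is.na(filled)] <-
          wmean[as.character(nights$window_index[rows][is.na(filled)])]
      }
      x[is.na(x)] <- filled[is.na(x)]
      nights[rows, f] <- x
    }
  }
  windows$nights <- nights
  windows
}

#' Per-participant per-window median features
#'
#' The clustering unit: for every participant and analysis window, the
#' per-feature median over the window's (imputed) nights.
#'
#' @param windows Completed output of [impute_rolling_mean()].
#' @return `data.frame` with `participant_id`, `window_index`,
#'   `n_missing_nights` (pre-imputation count) and the ten feature medians in
#'   [sleep_features()] order.
#' @export
compute_window_medians <- function(windows) {
  nights <- windows$nights
  if (!nrow(nights)) stop("no nights to summarise", call. = FALSE)
  if (anyNA(nights[, sleep_features()]))
    stop("nights must be imputed before taking medians", call. = FALSE)
  key <- interaction(nights$participant_id, nights$window_index, drop = TRUE)
  med <- do.call(rbind, lapply(split(seq_len(nrow(nights)), key), function(ix) {
    vapply(sleep_features(), function(f) stats::median(nights[ix, f]),
           numeric(1))
  }))
  first <- !duplicated(key)
  out <- data.frame(participant_id = nights$participant_id[first],
                    window_index = nights$window_index[first],
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$window_index), ]
  med <- med[paste(out$participant_id, out$window_index, sep = "."), ,
             drop = FALSE]
  mc <- windows$missing_counts
  out$n_missing_nights <- mc$n_missing[match(
    paste(out$participant_id, out$window_index),
    paste(mc$participant_id, mc$window_index))]
  out <- cbind(out, as.data.frame(med))
  rownames(out) <- NULL
  out
}

#' Winsorise a feature matrix
#'
#' Per column, values below the lower quantile (above the upper quantile) are
#' clipped to that quantile. Row and column counts are unchanged.
#'
#' @param x Numeric matrix or data frame (rows = samples).
#' @param limits Length-2 quantile limits, default `c(0.05, 0.95)`.
#' @return Matrix of the same dimensions.
#' @export
winsorise <- function(x, limits = c(0.05, 0.95)) {
  x <- as.matrix(x)
  for (j in seq_len(ncol(x))) {
    q <- stats::quantile(x[, j], limits, names = FALSE)
    x[, j] <- pmin(pmax(x[, j], q[1]), q[2])
  }
  x
}

#' Z-score a feature matrix
#'
#' Columns are centered to mean 0 and scaled to unit population SD (divisor
#' `n`). The scaling parameters are returned for reuse; constant columns map
#' to all zeros with a warning.
#'
#' @param x Numeric matrix or data frame with at least 2 rows.
#' @return List with `scaled` matrix, `center` and `scale` vectors.
#' @export
zscore <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("zscore needs at least 2 rows", call. = FALSE)
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2L, center)^2))
  if (any(scale == 0)) {
    warning("constant columns mapped to zeros: ",
            paste(colnames(x)[scale == 0], collapse = ", "))
    scale[scale == 0] <- 1
  }
  list(scaled = sweep(sweep(x, 2L, center), 2L, scale, `/`),
       center = center, scale = scale)
}

#' Invert a z-score transform
#'
#' @param scaled Matrix returned in `zscore()$scaled`.
#' @param fit The full [zscore()] result (holds `center` and `scale`).
#' @return The original-scale matrix.
#' @export
zscore_invert <- function(scaled, fit) {
  sweep(sweep(as.matrix(scaled), 2L, fit$scale, `*`), 2L, fit$center, `+`)
}

#' Nightly records to window samples
#'
#' Runs the preprocessing chain — window extraction, missingness filter,
#' rolling-mean imputation, window medians — and attaches cohort metadata.
#' Winsorisation and z-scaling are deliberately left to fold assembly
#' ([assemble_fold()]) because they are fit on each combined fold matrix.
#'
#' @param nights Nightly records.
#' @param participants Participant table with `participant_id`, `cohort`,
#'   `age`, `sex`.
#' @param config A [pipeline_config()].
#' @return List with `window_samples` (one row per retained participant and
#'   window), `exclusions`, `flagged` and `threshold_nights`.
#' @export
#' @examples
#' co <- simulate_sleep_cohort(generator_config(n_plwd = 6, n_gp_pool = 6,
#'                                              seed = 3))
#' pre <- preprocess_nights(co$nights, co$participants, pipeline_config())
#' head(pre$window_samples[, 1:6])
preprocess_nights <- function(nights, participants, config = pipeline_config()) {
  win <- extract_windows(nights, config)
  filt <- apply_missingness_filter(win, config)
  win$nights <- win$nights[win$nights$participant_id %in% filt$retained, ,
                           drop = FALSE]
  win$missing_counts <- win$missing_counts[
    win$missing_counts$participant_id %in% filt$retained, , drop = FALSE]
  win <- impute_rolling_mean(win, config)
  ws <- compute_window_medians(win)
  m <- match(ws$participant_id, participants$participant_id)
  ws <- cbind(ws[, 1, drop = FALSE],
              cohort = participants$cohort[m],
              age = participants$age[m],
              sex = participants$sex[m],
              ws[, -1, drop = FALSE])
  list(window_samples = ws, exclusions = filt$exclusions,
       flagged = win$flagged, threshold_nights = filt$threshold_nights)
}
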