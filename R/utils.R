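#' Canonical nightly feature names
#'
#' The ten nightly summary features used throughout the pipeline, in the fixed
#' column order every matrix and CSV in the package follows: the four sleep
#' stage/wake durations in seconds, then nocturnal heart rate (beats/min) and
#' respiratory rate (breaths/min) min/avg/max triplets.
#'
#' @return Character vector of length 10.
#' @export
#' @examples
#' sleep_features()
sleep_features <- function() {
  c("nrem_s", "rem_s", "light_s", "waso_s",
    "hr_min", "hr_avg", "hr_max",
    "rr_min", "rr_avg", "rr_max")
}

# duration columns are truncated at zero; vitals triplets keep min <= avg <= max
.duration_features <- function() c("nrem_s", "rem_s", "light_s", "waso_s")

#' Derive per-stage seeds from one global seed
#'
#' A single user-facing seed is expanded into reproducible per-stage seeds so
#' each pipeline stage can be rerun in isolation with the same stream.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return A single integer seed, deterministic in `(seed, stage)`, < 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, length(stage) == 1L)
  # fold the md5 of "seed/stage" into a 31-bit integer
  s <- strtoi(substr(digest_chr(paste0(seed, "/", stage)), 1, 7), 16L)
  as.integer(s %% .Machine$integer.max)
}

# md5 of a string without touching the filesystem is not in base R's API for
# character input, so hash via a temp-free serialization fallback
digest_chr <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

.assert_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop(sprintf("%s must lie in [0, 1]", name), call. = FALSE)
  invisible(x)
}

.assert_feature_cols <- function(df, where) {
  miss <- setdiff(sleep_features(), names(df))
  if (length(miss))
    stop(sprintf("%s is missing feature columns: %s", where,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(df)
}

# largest-remainder apportionment of `total` across non-negative weights;
# ties broken by position so the result is deterministic
largest_remainder <- function(weights, total) {
  stopifnot(all(weights >= 0), total >= 0)
  if (sum(weights) == 0) {
    out <- integer(length(weights))
    return(out)
  }
  q <- weights / sum(weights) * total
  base <- floor(q)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(q - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}
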