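#' Load a pipeline configuration from YAML
#'
#' The file may hold four sections — `generator`, `pipeline`, `folds`,
#' `clustering` — whose keys are the arguments of [generator_config()],
#' [pipeline_config()], [fold_plan()] and the sweep settings
#' (`algorithms`, `k_min`, `k_max`, `n_runs`). Omitted keys take the
#' documented defaults; unknown keys are rejected.
#'
#' @param path YAML file path, or `NULL` for an all-defaults configuration.
#' @return List with `generator`, `pipeline`, `plan` and `clustering`.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  known_sections <- c("generator", "pipeline", "folds", "clustering")
  unknown <- setdiff(names(raw), known_sections)
  if (length(unknown))
    stop("unknown config sections: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  build <- function(section, fn) {
    args <- raw[[section]]
    if (is.null(args)) args <- list()
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad))
      stop(sprintf("unknown keys in '%s': %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    do.call(fn, args)
  }
  cl <- raw$clustering
  if (is.null(cl)) cl <- list()
  bad <- setdiff(names(cl), c("algorithms", "k_min", "k_max", "n_runs"))
  if (length(bad))
    stop("unknown keys in 'clustering': ", paste(bad, collapse = ", "),
         call. = FALSE)
  clustering <- list(
    algorithms = cl$algorithms %||% c("kmeans", "gmm", "agglomerative"),
    k_range = seq.int(cl$k_min %||% 2L, cl$k_max %||% 25L),
    n_runs = cl$n_runs %||% 15L)
  list(generator = build("generator", generator_config),
       pipeline = build("pipeline", pipeline_config),
       plan = build("folds", fold_plan),
       clustering = clustering)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a nightly-records CSV
#'
#' Schema and plausibility checks: required columns, parseable ISO-8601
#' dates, one record per (participant, date), heart/respiratory-rate triplet
#' ordering, non-negative durations, and unit plausibility (heart rate above
#' 300 beats/min or respiratory rate above 80 breaths/min is flagged as a
#' warning-level issue). Missing nights (all features empty) are legal.
#'
#' @param path CSV path.
#' @return `data.frame` of issues (`severity`, `participant_id`,
#'   `night_date`, `message`); zero rows when the file is well formed.
#' @export
validate_night_csv <- function(path) {
  issues <- list()
  add <- function(severity, id, date, msg)
    issues[[length(issues) + 1L]] <<- data.frame(
      severity = severity, participant_id = id, night_date = as.character(date),
      message = msg, stringsAsFactors = FALSE)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "night_date", sleep_features())
  miss <- setdiff(need, names(d))
  if (length(miss)) {
    add("error", NA, NA, paste("missing columns:", paste(miss, collapse = ", ")))
    return(do.call(rbind, issues))
  }
  dates <- as.Date(d$night_date, format = "%Y-%m-%d")
  bad_date <- is.na(dates) & !is.na(d$night_date) & nzchar(d$night_date)
  for (i in which(bad_date))
    add("error", d$participant_id[i], d$night_date[i], "unparseable date")
  dup <- duplicated(d[, c("participant_id", "night_date")])
  for (i in which(dup))
    add("error", d$participant_id[i], d$night_date[i],
        "duplicate (participant, date) record")
  present <- !apply(is.na(d[, sleep_features()]), 1L, any)
  chk <- function(cond, msg, severity = "error") {
    for (i in which(present & cond))
      add(severity, d$participant_id[i], d$night_date[i], msg)
  }
  chk(d$hr_min > d$hr_avg | d$hr_avg > d$hr_max,
      "heart-rate triplet violates min <= avg <= max")
  chk(d$rr_min > d$rr_avg | d$rr_avg > d$rr_max,
      "respiratory-rate triplet violates min <= avg <= max")
  chk(d$nrem_s < 0 | d$rem_s < 0 | d$light_s < 0 | d$waso_s < 0,
      "negative duration")
  chk(d$hr_max > 300, "implausible heart rate (> 300 bpm)", "warning")
  chk(d$rr_max > 80, "implausible respiratory rate (> 80 brpm)", "warning")
  if (!length(issues))
    return(data.frame(severity = character(0), participant_id = character(0),
                      night_date = character(0), message = character(0)))
  do.call(rbind, issues)
}

.write_stage_csv <- function(d, path) {
  utils::write.csv(d, path, row.names = FALSE, na = "")
  path
}

#' Run the full pipeline and write its interface files
#'
#' Executes simulate (when no input CSVs are configured), preprocess,
#' fold-sampling, clustering and profiling in order, writing each stage's
#' files under `out_dir`, plus a run manifest recording the configuration
#' snapshot, per-stage seeds, package version and an md5 digest of every
#' output file. Identical configuration and seed reproduce byte-identical
#' files and manifest; wall-clock stage timings go to a separate
#' `timings.json` so the manifest itself stays deterministic.
#'
#' @param config A configuration list from [load_config()] (or `NULL` for
#'   defaults).
#' @param seed Global integer seed.
#' @param out_dir Output directory.
#' @param nights,participants Optional pre-existing input tables; when given,
#'   the simulate stage is skipped.
#' @param quiet Suppress progress messages.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config = NULL, seed = 1L, out_dir,
                         nights = NULL, participants = NULL, quiet = TRUE) {
  if (is.null(config)) config <- load_config(NULL)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(...)
  files <- character(0)
  timings <- list()
  stage <- function(name, expr) {
    say("stage: ", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e) {
      writeLines(conditionMessage(e), file.path(out_dir, paste0(name, ".failed")))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  if (is.null(nights) || is.null(participants)) {
    cohort <- stage("simulate", {
      gc <- config$generator
      gc$seed <- derive_seed(seed, "generator")
      simulate_sleep_cohort(gc)
    })
    files <- c(files, write_sleep_cohort(cohort, out_dir))
    nights <- cohort$nights
    participants <- cohort$participants
  }
  fit <- stage("fit", {
    plan <- config$plan
    plan$seed <- derive_seed(seed, "folds")
    sleep_phenotypes(nights, participants, config = config$pipeline,
                     plan = plan,
                     algorithms = config$clustering$algorithms,
                     k_range = config$clustering$k_range,
                     n_boot = config$clustering$n_runs, seed = seed)
  })
  files <- c(files, stage("write", {
    ws_path <- .write_stage_csv(fit$window_samples,
                                file.path(out_dir, "window_samples.csv"))
    ex_path <- .write_stage_csv(fit$preprocessing$exclusions,
                                file.path(out_dir, "exclusions.csv"))
    jsonlite::write_json(
      list(seed = fit$plan$seed,
           folds = stats::setNames(fit$fold_sets$folds,
                                   paste0("fold_", seq_along(fit$fold_sets$folds))),
           per_fold = fit$plan$per_fold),
      file.path(out_dir, "folds.json"), auto_unbox = TRUE, digits = NA)
    sel_path <- .write_stage_csv(fit$selection,
                                 file.path(out_dir, "selection_table.csv"))
    cl_paths <- vapply(seq_along(fit$assignments), function(i)
      .write_stage_csv(fit$assignments[[i]][, c("participant_id", "cohort",
                                                "window_index", "cluster")],
                       file.path(out_dir, sprintf("clusters_fold_%d.csv", i))),
      character(1))
    jsonlite::write_json(fit$model, file.path(out_dir, "model.json"),
                         auto_unbox = TRUE, digits = NA)
    pr_path <- .write_stage_csv(fit$profiles,
                                file.path(out_dir, "profiles.csv"))
    stats_rows <- do.call(rbind, lapply(names(fit$feature_stats), function(f) {
      st <- fit$feature_stats[[f]]
      data.frame(feature = f, f_value = st$anova$statistic,
                 df1 = st$anova$df[1], df2 = st$anova$df[2],
                 p_value = st$anova$p_value)
    }))
    st_path <- .write_stage_csv(stats_rows,
                                file.path(out_dir, "stats_features.csv"))
    c(ws_path, ex_path, file.path(out_dir, "folds.json"), sel_path, cl_paths,
      file.path(out_dir, "model.json"), pr_path, st_path)
  }))
  snapshot <- rapply(list(generator = unclass(config$generator),
                          pipeline = unclass(config$pipeline),
                          plan = unclass(config$plan),
                          clustering = config$clustering),
                     function(x) if (inherits(x, "Date"))
                       format(x, "%Y-%m-%d") else x,
                     how = "replace")
  manifest <- list(
    package = "sleepclust",
    version = as.character(utils::packageVersion("sleepclust")),
    seed = seed,
    stage_seeds = list(generator = derive_seed(seed, "generator"),
                       folds = derive_seed(seed, "folds"),
                       sweep = derive_seed(seed, "sweep")),
    config = snapshot,
    model = fit$model,
    files = as.list(stats::setNames(unname(tools::md5sum(sort(unname(files)))),
                                    basename(sort(unname(files))))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(timings, file.path(out_dir, "timings.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
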