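#' Fit the sleep phenotyping model
#'
#' End-to-end fit from nightly records to harmonized cluster phenotypes:
#' preprocesses nights into 30-day median window samples, draws age-matched
#' disjoint general-population folds, sweeps the three clustering algorithms
#' over `k_range` with bootstrap validity indices on the sweep fold, selects
#' the best (algorithm, k) by silhouette, fits the selected model to every
#' fold, harmonizes labels by centroid-origin distance, and profiles the
#' clusters demographically and statistically.
#'
#' @param nights Nightly records (`participant_id`, `night_date`, the ten
#'   [sleep_features()] columns; missing nights as `NA`).
#' @param participants Participant table (`participant_id`, `cohort`, `age`,
#'   `sex`, optional `mmse`).
#' @param config A [pipeline_config()].
#' @param plan A [fold_plan()], or `NULL` to build one with a seed derived
#'   from `seed`.
#' @param algorithms Clustering algorithms to compare.
#' @param k_range Cluster counts to sweep (default `2:25`).
#' @param n_boot Bootstrap refits per sweep cell (default 15).
#' @param sweep_fold Fold whose combined matrix drives model selection.
#' @param seed Global seed; every stochastic stage derives its own stream
#'   from it.
#' @return An object of class `sleep_phenotypes`; see [print.sleep_phenotypes()],
#'   [summary.sleep_phenotypes()], [coef.sleep_phenotypes()],
#'   [fitted.sleep_phenotypes()] and [plot.sleep_phenotypes()].
#' @export
#' @examples
#' \donttest{
#' co <- simulate_sleep_cohort(generator_config(n_plwd = 12, n_gp_pool = 60,
#'                                              frac_excludable = 0, seed = 2))
#' fit <- sleep_phenotypes(co$nights, co$participants,
#'                         plan = fold_plan(n_folds = 2, per_fold = 12),
#'                         k_range = 2:4, n_boot = 3, seed = 2)
#' print(fit)
#' }
sleep_phenotypes <- function(nights, participants,
                             config = pipeline_config(), plan = NULL,
                             algorithms = c("kmeans", "gmm", "agglomerative"),
                             k_range = 2:25, n_boot = 15L, sweep_fold = 1L,
                             seed = 1L) {
  pre <- preprocess_nights(nights, participants, config)
  ws <- pre$window_samples
  plwd_ws <- ws[ws$cohort == "PLWD", , drop = FALSE]
  gp_ws <- ws[ws$cohort == "GP", , drop = FALSE]
  if (!nrow(plwd_ws) || !nrow(gp_ws))
    stop("both cohorts must survive preprocessing", call. = FALSE)
  if (is.null(plan))
    plan <- fold_plan(seed = derive_seed(seed, "folds"))
  plwd_people <- participants[participants$participant_id %in%
                                plwd_ws$participant_id, , drop = FALSE]
  gp_people <- participants[participants$participant_id %in%
                              gp_ws$participant_id, , drop = FALSE]
  reference <- build_age_reference(plwd_people, plan$age_bins)
  fold_sets <- sample_folds(gp_people, reference, plan)
  fold_data <- lapply(seq_len(plan$n_folds), function(i) {
    assemble_fold(plwd_ws,
                  gp_ws[gp_ws$participant_id %in% fold_sets$folds[[i]], ,
                        drop = FALSE],
                  config, fold_index = i)
  })
  selection <- sweep_models(fold_data[[sweep_fold]]$x, algorithms, k_range,
                            n_runs = n_boot, seed = derive_seed(seed, "sweep"))
  sel <- select_model(selection)
  fits <- lapply(seq_along(fold_data), function(i) {
    fit_cluster_model(fold_data[[i]]$x, sel$algorithm, sel$k,
                      seed = derive_seed(seed, paste0("fit", i)))
  })
  maps <- harmonize_labels(lapply(fits, `[[`, "centroids"))
  assignments <- lapply(seq_along(fold_data), function(i) {
    d <- fold_data[[i]]$meta
    d$cluster <- apply_label_map(fits[[i]]$labels, maps[[i]])
    cbind(d, as.data.frame(fold_data[[i]]$x))
  })
  profiles <- profile_clusters(assignments)
  pooled <- do.call(rbind, assignments)
  feature_stats <- lapply(stats::setNames(nm = sleep_features()), function(f) {
    list(anova = one_way_anova(pooled[[f]], pooled$cluster),
         tukey = if (length(unique(pooled$cluster)) >= 2L)
           tukey_hsd(pooled[[f]], pooled$cluster) else NULL)
  })
  a1 <- assignments[[1]]
  long <- data.frame(
    value = unlist(a1[, sleep_features()], use.names = FALSE),
    metric = rep(sleep_features(), each = nrow(a1)),
    cluster = rep(a1$cluster, times = 10L),
    subject = rep(seq_len(nrow(a1)), times = 10L))
  rm_anova <- two_way_rm_anova(long)
  mmse_anova <- NULL
  if ("mmse" %in% names(participants)) {
    modal <- tapply(a1$cluster[a1$cohort == "PLWD"],
                    a1$participant_id[a1$cohort == "PLWD"],
                    function(v) as.integer(names(which.max(table(v)))))
    mm <- participants$mmse[match(names(modal), participants$participant_id)]
    keep <- !is.na(mm)
    if (sum(keep) >= 4L && length(unique(modal[keep])) >= 2L &&
        all(table(modal[keep]) >= 2L))
      mmse_anova <- one_way_anova(mm[keep], modal[keep])
  }
  structure(list(call = match.call(), config = config, plan = plan,
                 preprocessing = pre[c("exclusions", "flagged",
                                       "threshold_nights")],
                 window_samples = ws, fold_sets = fold_sets,
                 fold_data = fold_data, selection = selection,
                 model = sel[c("algorithm", "k")], fits = fits,
                 label_maps = maps, assignments = assignments,
                 profiles = profiles, feature_stats = feature_stats,
                 rm_anova = rm_anova, mmse_anova = mmse_anova, seed = seed),
            class = "sleep_phenotypes")
}

#' @describeIn sleep_phenotypes Brief description of the fitted model.
#' @param x,object A `sleep_phenotypes` fit.
#' @param ... Unused.
#' @export
print.sleep_phenotypes <- function(x, ...) {
  cat("Sleep phenotyping fit\n")
  cat(sprintf("  window samples: %d (%d PLWD, %d GP pool)\n",
              nrow(x$window_samples),
              sum(x$window_samples$cohort == "PLWD"),
              sum(x$window_samples$cohort == "GP")))
  cat(sprintf("  folds: %d x %d GP participants, combined %d rows each\n",
              x$plan$n_folds, x$plan$per_fold, nrow(x$fold_data[[1]]$x)))
  cat(sprintf("  selected model: %s, k = %d (silhouette %.3f)\n",
              x$model$algorithm, x$model$k, x$selection$sc[
                x$selection$algorithm == x$model$algorithm &
                  x$selection$k == x$model$k]))
  invisible(x)
}

#' @describeIn sleep_phenotypes Selection table head and cluster profiles.
#' @export
summary.sleep_phenotypes <- function(object, ...) {
  out <- list(model = object$model,
              selection = utils::head(select_model(object$selection)$audit, 5L),
              profiles = object$profiles,
              exclusions = object$preprocessing$exclusions)
  class(out) <- "summary.sleep_phenotypes"
  out
}

#' @export
print.summary.sleep_phenotypes <- function(x, ...) {
  cat(sprintf("Selected model: %s, k = %d\n\n", x$model$algorithm, x$model$k))
  cat("Top of the selection table (by silhouette):\n")
  print(x$selection[, c("algorithm", "k", "sc", "sc_lo", "sc_hi", "ch", "db")],
        digits = 3, row.names = FALSE)
  cat("\nCluster profiles (mean +/- SEM across folds):\n")
  cols <- c("cluster", "n_mean", "pct_plwd", "pct_plwd_sem", "pct_female",
            "pct_female_sem", "mean_age", "mean_age_sem")
  print(x$profiles[, cols], digits = 4, row.names = FALSE)
  if (nrow(x$exclusions)) {
    cat(sprintf("\n%d participant(s) excluded by the missingness filter\n",
                nrow(x$exclusions)))
  }
  invisible(x)
}

#' @describeIn sleep_phenotypes Harmonized cluster centroids (scaled space),
#'   averaged across folds.
#' @export
coef.sleep_phenotypes <- function(object, ...) {
  k <- object$model$k
  acc <- matrix(0, k, length(sleep_features()),
                dimnames = list(paste0("cluster_", seq_len(k)),
                                sleep_features()))
  for (i in seq_along(object$fits)) {
    cen <- object$fits[[i]]$centroids
    acc[object$label_maps[[i]], ] <- acc[object$label_maps[[i]], ] + cen
  }
  acc / length(object$fits)
}

#' @describeIn sleep_phenotypes Per-fold harmonized cluster assignments
#'   (list of data frames with row metadata and a `cluster` column).
#' @export
fitted.sleep_phenotypes <- function(object, ...) {
  lapply(object$assignments, function(d)
    d[, c("participant_id", "cohort", "age", "sex", "window_index",
          "cluster")])
}

#' @describeIn sleep_phenotypes Base-graphics profile plot: per-cluster
#'   cohort split and scaled feature means.
#' @export
plot.sleep_phenotypes <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 3, 1))
  on.exit(graphics::par(op))
  pr <- x$profiles
  comp <- rbind(PLWD = pr$pct_plwd, GP = pr$pct_gp)
  colnames(comp) <- paste("cluster", pr$cluster)
  graphics::barplot(comp, beside = TRUE, ylab = "% of cluster (mean over folds)",
                    legend.text = TRUE, main = "Cohort composition",
                    args.legend = list(x = "topright", bty = "n"))
  cen <- t(coef(x))
  graphics::barplot(t(cen), beside = TRUE, las = 2,
                    ylab = "scaled feature mean",
                    main = sprintf("%s centroids (k = %d)",
                                   x$model$algorithm, x$model$k))
  invisible(x)
}
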