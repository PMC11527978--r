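.stat_result <- function(test, statistic, df, p_value, pairwise = NULL,
                         extra = list()) {
  structure(c(list(test = test, statistic = statistic, df = df,
                   p_value = p_value, pairwise = pairwise), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic, digits = 4),
      ", df = ", paste(format(x$df, digits = 4), collapse = ", "),
      ", p = ", format(x$p_value, digits = 3), "\n", sep = "")
  if (!is.null(x$pairwise)) {
    cat("pairwise comparisons:\n")
    print(x$pairwise, digits = 4)
  }
  invisible(x)
}

.sem <- function(v) if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else 0

#' Demographic and feature profiles of harmonized clusters
#'
#' Per fold and harmonized cluster, computes cohort and sex percentages, mean
#' age and (optionally) mean scaled feature values over the cluster's rows,
#' then aggregates each quantity as mean +/- SEM across folds (SEM = sample
#' SD of the fold values / sqrt(number of folds contributing)). A cluster
#' absent from a fold contributes no value for that fold and the SEM
#' denominator adjusts.
#'
#' @param fold_assignments List with one `data.frame` per fold, holding a
#'   `cluster` column (harmonized labels), `cohort` (`"PLWD"`/`"GP"`), `sex`
#'   (`"M"`/`"F"`), `age`, and optionally scaled feature columns named as in
#'   [sleep_features()].
#' @return `data.frame`, one row per cluster: `n_folds_present`, `n_mean`
#'   (rows per fold), and `<quantity>` / `<quantity>_sem` columns for
#'   `pct_plwd`, `pct_gp`, `pct_male`, `pct_female`, `mean_age` and any
#'   feature means.
#' @export
profile_clusters <- function(fold_assignments) {
  feats <- intersect(sleep_features(), names(fold_assignments[[1]]))
  per_fold <- lapply(fold_assignments, function(d) {
    do.call(rbind, lapply(split(d, d$cluster), function(g) {
      out <- data.frame(cluster = g$cluster[1], n = nrow(g),
                        pct_plwd = 100 * mean(g$cohort == "PLWD"),
                        pct_gp = 100 * mean(g$cohort == "GP"),
                        pct_male = 100 * mean(g$sex == "M"),
                        pct_female = 100 * mean(g$sex == "F"),
                        mean_age = mean(g$age))
      for (f in feats) out[[paste0("mean_", f)]] <- mean(g[[f]])
      out
    }))
  })
  all_rows <- do.call(rbind, per_fold)
  qty <- setdiff(names(all_rows), c("cluster", "n"))
  do.call(rbind, lapply(split(all_rows, all_rows$cluster), function(g) {
    out <- data.frame(cluster = g$cluster[1],
                      n_folds_present = nrow(g), n_mean = mean(g$n))
    for (q in qty) {
      out[[q]] <- mean(g[[q]])
      out[[paste0(q, "_sem")]] <- .sem(g[[q]])
    }
    out
  }))
}

#' One-way analysis of variance
#'
#' `F = MS_between / MS_within` on `(k - 1, N - k)` degrees of freedom. The
#' fully degenerate case (all values identical) returns `F = 0`, `p = 1`;
#' zero within-group variance with distinct group means returns `F = Inf`,
#' `p = 0`, flagged in the result.
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups, each with >= 2 values).
#' @return A `stat_result` with `statistic` (F), `df = c(k - 1, N - k)` and
#'   `p_value`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(table(groups) < 2L)) stop("every group needs >= 2 values",
                                    call. = FALSE)
  # a perfect fit warns in anova.lm; the degenerate cases are handled below
  tab <- suppressWarnings(stats::anova(stats::lm(values ~ groups)))
  f <- tab$`F value`[1]
  p <- tab$`Pr(>F)`[1]
  degenerate <- FALSE
  tiny <- .Machine$double.eps * sum(values^2 + 1) * length(values)
  if (tab$`Sum Sq`[2] <= tiny) { # zero within-group variance
    degenerate <- TRUE
    if (tab$`Sum Sq`[1] <= tiny) {
      f <- 0; p <- 1       # all values identical
    } else {
      f <- Inf; p <- 0     # identical within groups, distinct means
    }
  }
  .stat_result("one_way_anova", f, df = tab$Df, p_value = p,
               extra = list(degenerate = degenerate))
}

#' Tukey's honest significant difference post-hoc test
#'
#' All pairwise mean differences with studentized-range adjusted p-values,
#' using the pooled within-group mean square; unequal group sizes use the
#' Tukey-Kramer harmonic-mean form (as `stats::TukeyHSD` does).
#'
#' @param values Numeric response.
#' @param groups Group labels (>= 2 groups).
#' @param alpha Family-wise level for the confidence bounds (default 0.05).
#' @return A `stat_result`; `pairwise` holds `k(k-1)/2` rows of
#'   (pair, diff, lwr, upr, p_adj).
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$groups
  pw <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                   lwr = tk[, "lwr"], upr = tk[, "upr"],
                   p_adj = tk[, "p adj"], row.names = NULL,
                   stringsAsFactors = FALSE)
  .stat_result("tukey_hsd", statistic = NA_real_,
               df = stats::df.residual(fit), p_value = min(pw$p_adj),
               pairwise = pw)
}

#' Independent-samples t test
#'
#' Two-sided; pooled-variance by default, Welch correction optional.
#'
#' @param values_a,values_b Numeric samples.
#' @param welch Use the Welch degrees-of-freedom correction.
#' @return A `stat_result` with `statistic` (t), `df` and `p_value`.
#' @export
t_test_independent <- function(values_a, values_b, welch = FALSE) {
  tt <- stats::t.test(values_a, values_b, var.equal = !welch)
  .stat_result("t_test_independent", unname(tt$statistic),
               df = unname(tt$parameter), p_value = tt$p.value,
               extra = list(mean_diff = unname(diff(rev(tt$estimate)))))
}

#' Two-way mixed (repeated-measures) analysis of variance
#'
#' Mixed design with one between-subject factor (e.g. cluster) and one
#' within-subject factor (e.g. sleep metric): the between effect is tested
#' against the subject-within-group stratum, the within effect and the
#' interaction against the subject-by-metric residual. Implemented as the
#' classical sum-of-squares partition via `stats::aov` with an
#' `Error(subject)` stratum. With a single within-factor level the design
#' collapses to [one_way_anova()] on the between factor.
#'
#' @param data Long-format `data.frame`.
#' @param value,between,within,subject Column names in `data`.
#' @return List of three `stat_result`s: `between`, `within`, `interaction`
#'   (the latter two `NULL` when the design collapses).
#' @export
two_way_rm_anova <- function(data, value = "value", between = "cluster",
                             within = "metric", subject = "subject") {
  d <- data.frame(y = data[[value]], B = factor(data[[between]]),
                  W = factor(data[[within]]), S = factor(data[[subject]]))
  cover <- table(d$S, d$W)
  bad <- rownames(cover)[apply(cover != 1L, 1L, any)]
  if (length(bad))
    stop("subjects without one value per within level: ",
         paste(bad, collapse = ", "), call. = FALSE)
  n_groups_per_subject <- tapply(as.character(d$B), d$S,
                                 function(v) length(unique(v)))
  if (any(n_groups_per_subject > 1L))
    stop("subjects must be nested in the between factor", call. = FALSE)
  if (nlevels(d$W) == 1L) {
    return(list(between = one_way_anova(d$y, d$B), within = NULL,
                interaction = NULL))
  }
  fit <- stats::aov(y ~ B * W + Error(S), data = d)
  sm <- summary(fit)
  tab_s <- sm[["Error: S"]][[1]]
  tab_w <- sm[["Error: Within"]][[1]]
  tiny <- .Machine$double.eps * sum(d$y^2 + 1) * length(d$y)
  grab <- function(tab, term, name) {
    i <- match(term, trimws(rownames(tab)))
    f <- tab$`F value`[i]
    p <- tab$`Pr(>F)`[i]
    if (tab$`Sum Sq`[i] <= tiny) { f <- 0; p <- 1 } # effect absent exactly
    else if (!is.finite(f)) { f <- Inf; p <- 0 }    # zero error stratum
    .stat_result(name, f, df = c(tab$Df[i], tab$Df[nrow(tab)]), p_value = p)
  }
  list(between = grab(tab_s, "B", "rm_anova_between"),
       within = grab(tab_w, "W", "rm_anova_within"),
       interaction = grab(tab_w, "B:W", "rm_anova_interaction"))
}
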