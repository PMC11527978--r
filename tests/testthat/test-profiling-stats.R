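# one fold's assignment table from explicit per-row attributes
fold_frame <- function(cluster, cohort, sex = NULL, age = NULL) {
  n <- length(cluster)
  data.frame(cluster = cluster, cohort = cohort,
             sex = if (is.null(sex)) rep("M", n) else sex,
             age = if (is.null(age)) rep(75, n) else age,
             stringsAsFactors = FALSE)
}

test_that("cluster profiles aggregate fold percentages as mean +/- SEM", {
  # homogeneous cluster: 100% PLWD in every fold, SEM 0
  folds <- lapply(1:5, function(i)
    fold_frame(cluster = rep(1:2, each = 4),
               cohort = c(rep("PLWD", 4), rep("GP", 4))))
  pr <- profile_clusters(folds)
  expect_equal(pr$pct_plwd[pr$cluster == 1], 100)
  expect_equal(pr$pct_plwd_sem[pr$cluster == 1], 0)
  expect_equal(pr$pct_gp[pr$cluster == 2], 100)
  # cohort and sex percentages are complementary within each cluster
  expect_equal(pr$pct_plwd + pr$pct_gp, c(100, 100))
  expect_equal(pr$pct_male + pr$pct_female, c(100, 100))

  # fold percentages (70, 72, 74, 71, 73) -> mean 72, SEM = sd / sqrt(5)
  pcts <- c(70, 72, 74, 71, 73)
  folds2 <- lapply(pcts, function(p)
    fold_frame(cluster = rep(1L, 100),
               cohort = c(rep("PLWD", p), rep("GP", 100 - p))))
  pr2 <- profile_clusters(folds2)
  expect_equal(pr2$pct_plwd, 72)
  expect_equal(pr2$pct_plwd_sem, sd(pcts) / sqrt(5))
})

test_that("a cluster absent from one fold adjusts the SEM denominator", {
  folds <- list(
    fold_frame(cluster = c(1, 1, 2, 2), cohort = rep("PLWD", 4)),
    fold_frame(cluster = c(1, 1, 2, 2), cohort = rep("PLWD", 4)),
    fold_frame(cluster = c(1, 1, 1, 1), cohort = rep("PLWD", 4)))
  pr <- profile_clusters(folds)
  expect_equal(pr$n_folds_present[pr$cluster == 2], 2)
  expect_equal(pr$n_folds_present[pr$cluster == 1], 3)
})

test_that("one-way ANOVA matches its F definition and degenerate conventions", {
  # all values equal -> F = 0, p = 1
  null_res <- one_way_anova(rep(5, 9), rep(letters[1:3], each = 3))
  expect_equal(null_res$statistic, 0)
  expect_equal(null_res$p_value, 1)

  # two groups: F equals the square of the pooled-variance t statistic
  set.seed(14)
  a <- rnorm(8, 1); b <- rnorm(10, 2)
  f2 <- one_way_anova(c(a, b), rep(c("a", "b"), c(8, 10)))
  t2 <- t_test_independent(a, b)
  expect_equal(f2$statistic, t2$statistic^2, tolerance = 1e-10)
  expect_equal(f2$p_value, t2$p_value, tolerance = 1e-10)

  # 3 x 4 toy table against the explicit sum-of-squares partition
  y <- c(3, 5, 4, 6,   8, 9, 7, 10,   1, 2, 2, 3)
  g <- rep(c("g1", "g2", "g3"), each = 4)
  res <- one_way_anova(y, g)
  gm <- mean(y)
  ss_b <- sum(tapply(y, g, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
  f_oracle <- (ss_b / 2) / (ss_w / 9)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$df, c(2, 9))
  expect_equal(res$p_value, pf(f_oracle, 2, 9, lower.tail = FALSE),
               tolerance = 1e-12)

  # shift invariance and scale invariance of F
  res_shift <- one_way_anova(y + 100, g)
  res_scale <- one_way_anova(y * 3.7, g)
  expect_equal(res$statistic, res_shift$statistic, tolerance = 1e-10)
  expect_equal(res$statistic, res_scale$statistic, tolerance = 1e-10)

  expect_error(one_way_anova(1:4, c("a", "a", "a", "b")), ">= 2 values")
})

test_that("Tukey HSD reduces to the plain comparison at k = 2 and bounds pairwise p", {
  set.seed(15)
  a <- rnorm(7, 0); b <- rnorm(9, 1)
  tk <- tukey_hsd(c(a, b), rep(c("a", "b"), c(7, 9)))
  expect_equal(nrow(tk$pairwise), 1L)
  tt <- t_test_independent(a, b)
  expect_equal(tk$pairwise$p_adj, tt$p_value, tolerance = 1e-8)

  # identical group means -> adjusted p ~ 1; k = 3 -> 3 pairwise rows
  y0 <- rep(c(1, 2, 3), times = 3)
  tk0 <- tukey_hsd(y0, rep(c("a", "b", "c"), each = 3))
  expect_equal(nrow(tk0$pairwise), 3L)
  expect_true(all(tk0$pairwise$p_adj > 0.999))

  # Tukey-adjusted p never undercuts the unadjusted pairwise p (k >= 3)
  for (i in 1:10) {
    set.seed(400 + i)
    y <- rnorm(18)
    g <- rep(c("a", "b", "c"), each = 6)
    tk <- tukey_hsd(y, g)
    for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
      praw <- t_test_independent(y[g == pair[1]], y[g == pair[2]])$p_value
      row <- grepl(pair[1], tk$pairwise$pair) & grepl(pair[2], tk$pairwise$pair)
      expect_gte(tk$pairwise$p_adj[row] + 1e-12, praw * 0.999)
    }
  }
})

test_that("independent t test matches the pooled formula and is antisymmetric", {
  null_res <- t_test_independent(c(1, 2, 3), c(1, 2, 3))
  expect_equal(null_res$statistic, 0)
  expect_equal(null_res$p_value, 1)

  res <- t_test_independent(c(1, 2, 3), c(4, 5, 6))
  # pooled: means 2 and 5, pooled var 1, se = sqrt(1 * (1/3 + 1/3))
  t_oracle <- (2 - 5) / sqrt(2 / 3)
  expect_equal(res$statistic, t_oracle, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(t_oracle, 4), tolerance = 1e-12)

  swapped <- t_test_independent(c(4, 5, 6), c(1, 2, 3))
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)

  set.seed(16)
  a <- rnorm(6); b <- rnorm(14, sd = 3)
  expect_false(isTRUE(all.equal(t_test_independent(a, b)$p_value,
                                t_test_independent(a, b, welch = TRUE)$p_value)))
})

test_that("mixed two-way RM ANOVA partitions sums of squares correctly", {
  # all values equal -> all F = 0
  d0 <- expand.grid(subject = paste0("s", 1:6), metric = c("m1", "m2"))
  d0$cluster <- rep(c("c1", "c2"), each = 3)[match(d0$subject,
                                                   paste0("s", 1:6))]
  d0$value <- 1
  r0 <- two_way_rm_anova(d0)
  expect_equal(r0$between$statistic, 0)
  expect_equal(r0$within$statistic, 0)
  expect_equal(r0$interaction$statistic, 0)

  # single within level collapses to the one-way ANOVA on the between factor
  set.seed(17)
  d1 <- data.frame(subject = paste0("s", 1:12),
                   cluster = rep(c("c1", "c2", "c3"), each = 4),
                   metric = "m1", value = rnorm(12))
  r1 <- two_way_rm_anova(d1)
  ow <- one_way_anova(d1$value, d1$cluster)
  expect_equal(r1$between$statistic, ow$statistic, tolerance = 1e-10)
  expect_equal(r1$between$p_value, ow$p_value, tolerance = 1e-10)
  expect_null(r1$within)

  # explicit SS oracle on a 2-cluster x 2-metric balanced design
  set.seed(18)
  n_per <- 4
  d2 <- expand.grid(subject = paste0("s", 1:(2 * n_per)),
                    metric = c("m1", "m2"), stringsAsFactors = FALSE)
  d2$cluster <- ifelse(as.integer(sub("s", "", d2$subject)) <= n_per,
                       "c1", "c2")
  d2$value <- rnorm(nrow(d2)) +
    2 * (d2$cluster == "c2") + 1.5 * (d2$metric == "m2") +
    1 * (d2$cluster == "c2" & d2$metric == "m2")
  r2 <- two_way_rm_anova(d2)

  gm <- mean(d2$value)
  subj_mean <- tapply(d2$value, d2$subject, mean)
  clus_mean <- tapply(d2$value, d2$cluster, mean)
  met_mean <- tapply(d2$value, d2$metric, mean)
  cell_mean <- tapply(d2$value, list(d2$cluster, d2$metric), mean)
  w <- 2 # within levels
  ss_between_cluster <- w * sum(n_per * (clus_mean - gm)^2)
  subj_cluster <- ifelse(as.integer(sub("s", "", names(subj_mean))) <= n_per,
                         "c1", "c2")
  ss_subj_within <- w * sum((subj_mean - clus_mean[subj_cluster])^2)
  ss_metric <- 2 * n_per * sum((met_mean - gm)^2)
  ss_inter <- n_per * sum((cell_mean - outer(clus_mean - gm, met_mean - gm,
                                             `+`) - gm)^2)
  ss_total <- sum((d2$value - gm)^2)
  ss_resid <- ss_total - ss_between_cluster - ss_subj_within - ss_metric -
    ss_inter
  df_subj <- 2 * n_per - 2
  f_between <- (ss_between_cluster / 1) / (ss_subj_within / df_subj)
  f_metric <- (ss_metric / 1) / (ss_resid / df_subj)
  f_inter <- (ss_inter / 1) / (ss_resid / df_subj)
  expect_equal(r2$between$statistic, f_between, tolerance = 1e-8)
  expect_equal(r2$within$statistic, f_metric, tolerance = 1e-8)
  expect_equal(r2$interaction$statistic, f_inter, tolerance = 1e-8)

  # incomplete within-level coverage names the offending subject
  expect_error(two_way_rm_anova(d2[-1, ]), "s1")
})
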