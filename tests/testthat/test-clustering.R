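test_that("k-means handles saturated k and separable groups", {
  set.seed(1)
  x <- matrix(rnorm(20), 10, 2)
  sat <- fit_kmeans(x, 10, seed = 1)
  expect_lt(sat$inertia, 1e-12)
  expect_equal(sort(sat$labels), 1:10)

  two <- rbind(matrix(0.01 * rnorm(20), 10, 2),
               matrix(9 + 0.01 * rnorm(20), 10, 2))
  fit <- fit_kmeans(two, 2, seed = 3)
  expect_equal(length(unique(fit$labels[1:10])), 1L)
  expect_equal(length(unique(fit$labels[11:20])), 1L)
  expect_false(fit$labels[1] == fit$labels[11])
  expect_error(fit_kmeans(two, 21, seed = 1), "exceeds")
})

test_that("k-means attains the optimum found by exhaustive bipartition", {
  set.seed(7)
  x <- matrix(rnorm(24, sd = 2), 12, 2)
  # enumerate all 2-cluster partitions of 12 points
  best <- Inf
  for (code in 1:(2^11 - 1)) {
    lab <- c(0L, as.integer(intToBits(code))[1:11])
    ss <- 0
    for (g in 0:1) {
      xi <- x[lab == g, , drop = FALSE]
      ss <- ss + sum(sweep(xi, 2, colMeans(xi))^2)
    }
    best <- min(best, ss)
  }
  fit <- fit_kmeans(x, 2, seed = 11)
  expect_equal(fit$inertia, best, tolerance = 1e-8)
})

test_that("GMM and agglomerative recover separable blobs; centroids are member means", {
  x <- blob_matrix(15, rbind(c(0, 0), c(9, 9)), sd = 0.3, seed = 4)
  truth <- rep(1:2, each = 15)
  for (fit in list(fit_gmm(x, 2, seed = 2), fit_agglomerative(x, 2))) {
    expect_equal(mclust::adjustedRandIndex(fit$labels, truth), 1)
    for (c in 1:2)
      expect_equal(fit$centroids[c, ],
                   colMeans(x[fit$labels == c, , drop = FALSE]))
  }
  singletons <- fit_agglomerative(x[1:6, ], 6)
  expect_equal(sort(singletons$labels), 1:6)
})

test_that("Ward merges follow the minimal-variance-increase sequence", {
  greedy_ward <- function(x, k_stop) {
    groups <- as.list(seq_len(nrow(x)))
    ss <- function(ix) {
      xi <- x[ix, , drop = FALSE]
      sum(sweep(xi, 2, colMeans(xi))^2)
    }
    while (length(groups) > k_stop) {
      best <- c(NA, NA, Inf)
      for (i in seq_along(groups)) for (j in seq_len(i - 1)) {
        inc <- ss(c(groups[[i]], groups[[j]])) - ss(groups[[i]]) - ss(groups[[j]])
        if (inc < best[3]) best <- c(i, j, inc)
      }
      merged <- c(groups[[best[1]]], groups[[best[2]]])
      groups <- c(groups[-c(best[1], best[2])], list(merged))
    }
    lab <- integer(nrow(x))
    for (g in seq_along(groups)) lab[groups[[g]]] <- g
    lab
  }
  set.seed(12)
  x <- matrix(rnorm(12), 6, 2)
  for (k in c(2, 3, 4)) {
    ours <- fit_agglomerative(x, k)$labels
    oracle <- greedy_ward(x, k)
    expect_equal(mclust::adjustedRandIndex(ours, oracle), 1)
  }
})

test_that("silhouette follows its conventions on degenerate inputs", {
  dup <- rbind(c(0, 0), c(0, 0), c(10, 10), c(10, 10))
  expect_equal(silhouette_score(dup, c(1, 1, 2, 2)), 1.0)
  x <- matrix(rnorm(10), 5, 2)
  expect_equal(silhouette_score(x, 1:5), 0.0) # all singletons
  expect_error(silhouette_score(x, rep(1, 5)), "2 clusters")
})

test_that("Calinski-Harabasz handles degenerate scatter and label permutations", {
  dup <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5), c(9, 0), c(9, 0))
  expect_equal(calinski_harabasz(dup, c(1, 1, 2, 2, 3, 3)), Inf)
  x <- matrix(rnorm(24), 12, 2)
  lab <- rep(1:3, each = 4)
  perm <- c(2L, 3L, 1L)[lab]
  expect_equal(calinski_harabasz(x, lab), calinski_harabasz(x, perm))
  expect_error(calinski_harabasz(x, 1:12), "2 <= k < n")
})

test_that("Davies-Bouldin is zero for point clusters and flags coincident centroids", {
  dup <- rbind(c(0, 0), c(0, 0), c(7, 1), c(7, 1))
  expect_equal(davies_bouldin(dup, c(1, 1, 2, 2)), 0)
  x <- matrix(rnorm(24), 12, 2)
  lab <- rep(1:3, each = 4)
  perm <- c(3L, 1L, 2L)[lab]
  expect_equal(davies_bouldin(x, lab), davies_bouldin(x, perm))
  # clusters {(1,0),(-1,0)} and {(0,1),(0,-1)} share the centroid (0,0)
  sym <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  expect_error(davies_bouldin(sym, c(1, 1, 2, 2)), "degenerate")
})

test_that("validity indices are invariant under rigid rotation", {
  set.seed(21)
  theta <- 0.83
  rot <- rbind(c(cos(theta), -sin(theta)), c(sin(theta), cos(theta)))
  for (i in 1:5) {
    inst <- random_instance(n = 15, k = 3, p = 2, seed = 100 + i)
    xr <- inst$x %*% rot
    expect_equal(silhouette_score(inst$x, inst$labels),
                 silhouette_score(xr, inst$labels), tolerance = 1e-10)
    expect_equal(calinski_harabasz(inst$x, inst$labels),
                 calinski_harabasz(xr, inst$labels), tolerance = 1e-10)
    expect_equal(davies_bouldin(inst$x, inst$labels),
                 davies_bouldin(xr, inst$labels), tolerance = 1e-10)
  }
})

test_that("silhouette agrees with the cluster package on random instances", {
  skip_if_not_installed("cluster")
  for (i in 1:10) {
    inst <- random_instance(n = 18, k = 3, p = 4, seed = 200 + i)
    ours <- silhouette_score(inst$x, inst$labels)
    ref <- mean(cluster::silhouette(inst$labels,
                                    dist(inst$x))[, "sil_width"])
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("bootstrap metric summaries have the promised shape and ordering", {
  x <- blob_matrix(12, rbind(c(0, 0), c(6, 6), c(0, 8)), sd = 0.4, seed = 5)
  ms <- bootstrap_metric_ci(x, "kmeans", 3, n_runs = 15, seed = 3)
  expect_equal(ms$n_runs, 15L)
  for (m in c("sc", "ch", "db")) {
    expect_lte(ms[[paste0(m, "_lo")]], ms[[paste0(m, "_boot")]])
    expect_lte(ms[[paste0(m, "_boot")]], ms[[paste0(m, "_hi")]])
  }
  expect_true(ms$sc >= -1 && ms$sc <= 1)
  expect_error(bootstrap_metric_ci(x, "kmeans", 3, n_runs = 1), "n_runs")

  # zero-variance clusters: every resample is identical, intervals collapse
  dup <- matrix(rep(rbind(c(0, 0), c(8, 8)), each = 10), 20, 2)
  dms <- bootstrap_metric_ci(dup, "agglomerative", 2, n_runs = 5, seed = 1)
  expect_equal(dms$sc_lo, dms$sc_hi)
  expect_equal(dms$sc, 1)
  expect_equal(dms$db, 0)
  expect_equal(dms$ch, Inf)
})

test_that("the sweep grid and selection rule behave as specified", {
  x <- blob_matrix(10, rbind(c(0, 0), c(7, 7), c(0, 9)), sd = 0.5, seed = 9)
  tab <- sweep_models(x, algorithms = c("kmeans", "agglomerative"),
                      k_range = 2:3, n_runs = 3, seed = 2)
  expect_equal(nrow(tab), 4L)
  one <- sweep_models(x, algorithms = "kmeans", k_range = 2:2, n_runs = 3,
                      seed = 2)
  expect_equal(nrow(one), 1L)
  expect_equal(select_model(one)[c("algorithm", "k")],
               list(algorithm = "kmeans", k = 2L))
  expect_warning(sweep_models(x[1:6, ], algorithms = "kmeans", k_range = 2:10,
                              n_runs = 2, seed = 1), "truncated")
  expect_error(select_model(tab[0, ]), "empty")

  # tie-breaking: equal SC falls through to CH, then DB
  tie <- data.frame(algorithm = c("a", "b", "c"), k = c(2L, 2L, 2L),
                    sc = c(0.5, 0.5, 0.4), ch = c(200, 300, 900),
                    db = c(1, 1, 1))
  expect_equal(select_model(tie)$algorithm, "b")
  ranked <- data.frame(algorithm = c("kmeans", "gmm", "agglomerative"),
                       k = 3L, sc = c(0.183, 0.122, 0.142),
                       ch = c(34.06, 40.70, 27.49), db = c(1.77, 1.96, 1.95))
  expect_equal(select_model(ranked)$algorithm, "kmeans")
})

test_that("label harmonization sorts by centroid norm with stable tie-breaks", {
  cen <- rbind(c(3.1, 0), c(0.5, 0), c(1.7, 0)) # norms 3.1, 0.5, 1.7
  maps <- harmonize_labels(list(cen))
  expect_equal(maps[[1]], c(3L, 1L, 2L))
  asc <- rbind(c(1, 0), c(2, 0), c(3, 0))
  expect_equal(harmonize_labels(list(asc))[[1]], 1:3)
  expect_equal(harmonize_labels(list(asc), decreasing = TRUE)[[1]], 3:1)
  # tied norms broken by coordinates, with a message, still a permutation
  tied <- rbind(c(0, 1), c(1, 0))
  expect_message(m <- harmonize_labels(list(tied)), "tied")
  expect_setequal(m[[1]], 1:2)
  expect_error(harmonize_labels(list(cen, asc[1:2, , drop = FALSE])),
               "same k")
  expect_equal(apply_label_map(c(1L, 3L, 2L, 1L), c(3L, 1L, 2L)),
               c(3L, 2L, 1L, 3L))
  expect_error(apply_label_map(1:2, c(2L, 2L)), "permutation")
})

test_that("k-means++ restarts never increase the kept inertia", {
  set.seed(31)
  x <- matrix(rnorm(60), 30, 2)
  i1 <- fit_kmeans(x, 3, seed = 5, n_init = 1)$inertia
  i10 <- fit_kmeans(x, 3, seed = 5, n_init = 10)$inertia
  expect_lte(i10, i1 + 1e-12)
})
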