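.check_labels <- function(x, labels) {
  n <- nrow(x)
  if (length(labels) != n) stop("labels/rows mismatch", call. = FALSE)
  k <- length(unique(labels))
  list(n = n, k = k)
}

#' Mean silhouette coefficient
#'
#' Per point, `s = (b - a) / max(a, b)` where `a` is the mean Euclidean
#' distance to the point's own-cluster co-members and `b` the smallest mean
#' distance to any other cluster. Points in singleton clusters score 0 (so
#' the all-singleton clustering scores 0). Returns the mean over points, in
#' `[-1, 1]`.
#'
#' @param x Numeric matrix (rows = samples).
#' @param labels Integer cluster labels with at least 2 distinct values.
#' @return Mean silhouette width.
#' @export
silhouette_score <- function(x, labels) {
  x <- as.matrix(x)
  chk <- .check_labels(x, labels)
  if (chk$k < 2L) stop("silhouette needs at least 2 clusters", call. = FALSE)
  d <- as.matrix(stats::dist(x))
  labs <- unique(labels)
  sizes <- stats::setNames(as.numeric(table(factor(labels, labs))), labs)
  # per point, sum of distances to each cluster
  sums <- vapply(labs, function(l) rowSums(d[, labels == l, drop = FALSE]),
                 numeric(chk$n))
  own <- match(labels, labs)
  s <- numeric(chk$n)
  for (i in seq_len(chk$n)) {
    nc <- sizes[own[i]]
    if (nc == 1) next # singleton convention: s = 0
    a <- sums[i, own[i]] / (nc - 1)
    b <- min(sums[i, -own[i]] / sizes[-own[i]])
    m <- max(a, b)
    s[i] <- if (m > 0) (b - a) / m else 0
  }
  mean(s)
}

#' Calinski-Harabasz index
#'
#' Ratio of between- to within-cluster dispersion,
#' `[sum_c n_c ||mu_c - mu||^2 / (k - 1)] / [sum_c sum_i ||x_i - mu_c||^2 / (n - k)]`.
#' Zero within-cluster scatter with distinct centroids returns `Inf`.
#'
#' @inheritParams silhouette_score
#' @return CH index (>= 0, possibly `Inf`).
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  chk <- .check_labels(x, labels)
  if (chk$k < 2L || chk$k >= chk$n)
    stop("Calinski-Harabasz needs 2 <= k < n", call. = FALSE)
  mu <- colMeans(x)
  labs <- unique(labels)
  between <- 0
  within <- 0
  for (l in labs) {
    xi <- x[labels == l, , drop = FALSE]
    mc <- colMeans(xi)
    between <- between + nrow(xi) * sum((mc - mu)^2)
    within <- within + sum(sweep(xi, 2L, mc)^2)
  }
  if (within == 0) return(Inf)
  (between / (chk$k - 1)) / (within / (chk$n - chk$k))
}

#' Davies-Bouldin index
#'
#' `(1/k) sum_c max_{c' != c} (S_c + S_c') / ||mu_c - mu_c'||`, with `S_c` the
#' mean distance of cluster members to their centroid. Lower is better; zero
#' scatter gives 0. Coincident centroids are a degenerate configuration and
#' raise an error.
#'
#' @inheritParams silhouette_score
#' @return DB index (>= 0).
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  chk <- .check_labels(x, labels)
  if (chk$k < 2L) stop("Davies-Bouldin needs at least 2 clusters",
                       call. = FALSE)
  labs <- unique(labels)
  k <- length(labs)
  cen <- matrix(0, k, ncol(x))
  s <- numeric(k)
  for (j in seq_len(k)) {
    xi <- x[labels == labs[j], , drop = FALSE]
    cen[j, ] <- colMeans(xi)
    s[j] <- mean(sqrt(rowSums(sweep(xi, 2L, cen[j, ])^2)))
  }
  dc <- as.matrix(stats::dist(cen))
  if (any(dc[upper.tri(dc)] == 0))
    stop("degenerate clustering: coincident centroids", call. = FALSE)
  r <- outer(s, s, `+`) / dc
  diag(r) <- -Inf
  mean(apply(r, 1L, max))
}

.metrics_for <- function(x, labels) {
  c(sc = silhouette_score(x, labels),
    ch = calinski_harabasz(x, labels),
    db = davies_bouldin(x, labels))
}

#' Bootstrap confidence intervals for the validity indices
#'
#' Fits the algorithm on the full matrix for point values, then `n_runs`
#' times resamples rows with replacement (same n), refits, and computes
#' SC/CH/DB on the resample. Reports the point value, bootstrap mean and
#' percentile 95\% interval per index. Resamples yielding an empty cluster or
#' a degenerate index are redrawn, up to a retry cap.
#'
#' @param x Scaled matrix.
#' @param algorithm `"kmeans"`, `"gmm"` or `"agglomerative"`.
#' @param k Cluster count.
#' @param n_runs Bootstrap refits (default 15).
#' @param seed Integer seed.
#' @param level Interval level (default 0.95).
#' @param max_retries Redraw cap per run.
#' @return One-row `data.frame`: `algorithm`, `k`, and for each of `sc`,
#'   `ch`, `db` the point value, `*_boot` mean, `*_lo` and `*_hi`.
#' @export
bootstrap_metric_ci <- function(x, algorithm, k, n_runs = 15L, seed = 1L,
                                level = 0.95, max_retries = 10L) {
  if (n_runs < 2L) stop("n_runs must be >= 2", call. = FALSE)
  x <- as.matrix(x)
  n <- nrow(x)
  point_fit <- fit_cluster_model(x, algorithm, k, seed = derive_seed(seed, "point"))
  point <- .metrics_for(x, point_fit$labels)
  set.seed(derive_seed(seed, paste0("boot_", algorithm, "_", k)))
  runs <- matrix(NA_real_, n_runs, 3L, dimnames = list(NULL, c("sc", "ch", "db")))
  for (r in seq_len(n_runs)) {
    for (try in seq_len(max_retries)) {
      idx <- sample.int(n, n, replace = TRUE)
      m <- tryCatch({
        fit <- fit_cluster_model(x[idx, , drop = FALSE], algorithm, k,
                                 seed = derive_seed(seed, paste0("run", r, ".", try)))
        .metrics_for(x[idx, , drop = FALSE], fit$labels)
      }, error = function(e) NULL)
      if (!is.null(m) && !anyNA(m)) { # Inf CH (zero within-scatter) is legal
        runs[r, ] <- m
        break
      }
    }
  }
  ok <- stats::complete.cases(runs)
  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  out <- data.frame(algorithm = algorithm, k = as.integer(k),
                    stringsAsFactors = FALSE)
  for (m in c("sc", "ch", "db")) {
    v <- runs[ok, m]
    out[[m]] <- unname(point[m])
    out[[paste0(m, "_boot")]] <- mean(v)
    ci <- stats::quantile(v, qs, names = FALSE)
    out[[paste0(m, "_lo")]] <- ci[1]
    out[[paste0(m, "_hi")]] <- ci[2]
  }
  out$n_runs <- sum(ok)
  out
}

#' Sweep algorithms and cluster counts
#'
#' Builds the model-selection table: one [bootstrap_metric_ci()] row per
#' (algorithm, k) cell. A `k_range` reaching beyond `n - 1` is truncated with
#' a warning.
#'
#' @param x Scaled matrix.
#' @param algorithms Algorithms to compare (default all three).
#' @param k_range Integer vector of cluster counts (default `2:25`).
#' @param n_runs Bootstrap refits per cell.
#' @param seed Integer seed.
#' @return `data.frame` selection table.
#' @export
sweep_models <- function(x, algorithms = c("kmeans", "gmm", "agglomerative"),
                         k_range = 2:25, n_runs = 15L, seed = 1L) {
  x <- as.matrix(x)
  if (max(k_range) > nrow(x) - 1L) {
    warning("k_range truncated to n - 1")
    k_range <- k_range[k_range <= nrow(x) - 1L]
  }
  rows <- list()
  for (alg in algorithms) {
    for (k in k_range) {
      rows[[length(rows) + 1L]] <- bootstrap_metric_ci(
        x, alg, k, n_runs = n_runs,
        seed = derive_seed(seed, paste0(alg, k)))
    }
  }
  do.call(rbind, rows)
}

#' Select the best (algorithm, k) from a sweep table
#'
#' Ranks by silhouette (higher better), breaking ties by Calinski-Harabasz
#' (higher), then Davies-Bouldin (lower), then table order. Ranking uses the
#' full-data point values; the bootstrap columns quantify stability.
#'
#' @param table Output of [sweep_models()].
#' @return List with `algorithm`, `k` and `audit` (the table in rank order).
#' @export
select_model <- function(table) {
  if (is.null(table) || !nrow(table)) stop("empty selection table",
                                           call. = FALSE)
  ord <- order(-table$sc, -table$ch, table$db, seq_len(nrow(table)))
  best <- table[ord[1L], ]
  list(algorithm = best$algorithm, k = best$k, audit = table[ord, ])
}

#' Harmonize cluster labels across folds by centroid-origin distance
#'
#' Within each fold, clusters are relabeled `1..k` by ascending Euclidean
#' distance of their centroid from the origin of the scaled feature space, so
#' the same phenotype gets the same label in every fold. Tied norms are
#' broken deterministically by the centroids' first coordinate (and
#' subsequent coordinates if needed), with a message.
#'
#' @param centroids_per_fold List of k x p centroid matrices (one per fold,
#'   same k).
#' @param decreasing Assign label 1 to the largest norm instead.
#' @return List of integer permutation maps; `map[old_label] = new_label`.
#' @export
harmonize_labels <- function(centroids_per_fold, decreasing = FALSE) {
  ks <- vapply(centroids_per_fold, nrow, integer(1))
  if (length(unique(ks)) != 1L)
    stop("all folds must share the same k", call. = FALSE)
  lapply(centroids_per_fold, function(cen) {
    norms <- sqrt(rowSums(cen^2))
    if (anyDuplicated(norms)) {
      message("tied centroid norms broken by coordinate order")
      ord <- do.call(order, c(list(norms), as.data.frame(cen),
                              list(decreasing = decreasing)))
    } else {
      ord <- order(norms, decreasing = decreasing)
    }
    map <- integer(length(norms))
    map[ord] <- seq_along(ord)
    map
  })
}

#' Apply a harmonization map to raw labels
#'
#' @param labels Integer labels in `1..k`.
#' @param map Permutation map from [harmonize_labels()].
#' @return Relabeled integer vector.
#' @export
apply_label_map <- function(labels, map) {
  if (!setequal(sort(unique(map)), seq_along(map)))
    stop("map must be a permutation", call. = FALSE)
  map[labels]
}
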