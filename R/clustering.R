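# Mclust resolves mclustBIC in the calling namespace, so both must be imported
#' @importFrom mclust Mclust mclustBIC priorControl
NULL

# k-means++ seeding: first center uniform, then points picked with probability
# proportional to squared distance to the nearest chosen center
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[centers[1L], ])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[j + 1L] <- sample.int(n, 1L)
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[j + 1L], ])^2))
  }
  x[centers, , drop = FALSE]
}

.member_centroids <- function(x, labels, k) {
  cen <- matrix(NA_real_, k, ncol(x), dimnames = list(NULL, colnames(x)))
  for (c in seq_len(k)) cen[c, ] <- colMeans(x[labels == c, , drop = FALSE])
  cen
}

.cluster_result <- function(algorithm, k, labels, x, seed = NA_integer_,
                            inertia = NA_real_) {
  labels <- as.integer(labels)
  if (any(tabulate(labels, k) == 0))
    stop("empty cluster in ", algorithm, " fit", call. = FALSE)
  structure(list(algorithm = algorithm, k = as.integer(k), labels = labels,
                 centroids = .member_centroids(x, labels, k),
                 inertia = inertia, seed = seed),
            class = "cluster_result")
}

#' K-means clustering (k-means++ seeding, Lloyd iterations, restarts)
#'
#' Lloyd's algorithm from k-means++ initial centers, repeated `n_init` times;
#' the restart with the lowest within-cluster sum of squares is kept.
#' Deterministic under `seed`.
#'
#' @param x Scaled numeric matrix (rows = samples).
#' @param k Number of clusters, `2 <= k <= nrow(x)`.
#' @param seed Integer seed.
#' @param n_init Number of restarts (default 10).
#' @param iter_max Maximum Lloyd iterations per restart.
#' @return A `cluster_result`: algorithm, `k`, integer `labels` in `1..k`,
#'   `centroids` (member means), `inertia`, `seed`.
#' @export
fit_kmeans <- function(x, k, seed = 1L, n_init = 10L, iter_max = 100L) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of rows", call. = FALSE)
  set.seed(derive_seed(seed, "kmeans"))
  best <- NULL
  for (r in seq_len(n_init)) {
    centers <- .kmeanspp_centers(x, k)
    fit <- tryCatch(
      stats::kmeans(x, centers = centers, iter.max = iter_max,
                    algorithm = "Lloyd"),
      error = function(e) NULL,
      warning = function(w) suppressWarnings(
        stats::kmeans(x, centers = centers, iter.max = iter_max,
                      algorithm = "Lloyd")))
    if (is.null(fit) || any(fit$size == 0)) next
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  if (is.null(best)) stop("k-means failed on all restarts", call. = FALSE)
  .cluster_result("kmeans", k, best$cluster, x, seed, best$tot.withinss)
}

#' Gaussian mixture model clustering
#'
#' Full-covariance Gaussian mixture fit by EM (via \pkg{mclust}), with a
#' conjugate prior regularizing the covariances against singularity. Labels
#' are the argmax responsibilities; centroids are member means so label
#' harmonization treats all algorithms alike.
#'
#' @inheritParams fit_kmeans
#' @return A `cluster_result`.
#' @export
fit_gmm <- function(x, k, seed = 1L) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of rows", call. = FALSE)
  set.seed(derive_seed(seed, "gmm"))
  fit <- suppressWarnings(
    mclust::Mclust(x, G = k, modelNames = "VVV",
                   prior = mclust::priorControl(), verbose = FALSE))
  if (is.null(fit))
    fit <- suppressWarnings(
      mclust::Mclust(x, G = k, modelNames = "EEI",
                     prior = mclust::priorControl(), verbose = FALSE))
  if (is.null(fit)) stop("GMM fit failed", call. = FALSE)
  .cluster_result("gmm", k, fit$classification, x, seed)
}

#' Ward agglomerative clustering
#'
#' Euclidean Ward linkage (`hclust` method `ward.D2`) cut at `k` clusters;
#' fully deterministic.
#'
#' @inheritParams fit_kmeans
#' @return A `cluster_result`.
#' @export
fit_agglomerative <- function(x, k) {
  x <- as.matrix(x)
  if (k > nrow(x)) stop("k exceeds the number of rows", call. = FALSE)
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  .cluster_result("agglomerative", k, stats::cutree(hc, k), x)
}

#' Fit one clustering algorithm by name
#'
#' @param x Scaled matrix.
#' @param algorithm `"kmeans"`, `"gmm"` or `"agglomerative"`.
#' @param k Cluster count.
#' @param seed Integer seed (ignored by the deterministic agglomerative fit).
#' @return A `cluster_result`.
#' @export
fit_cluster_model <- function(x, algorithm, k, seed = 1L) {
  switch(match.arg(algorithm, c("kmeans", "gmm", "agglomerative")),
         kmeans = fit_kmeans(x, k, seed),
         gmm = fit_gmm(x, k, seed),
         agglomerative = fit_agglomerative(x, k))
}
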