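# Small in-code fixtures shared across test files.

# a minimal two-phenotype spec set with controllable noise
tiny_specs <- function(between = 0, within = 0, sep = 4) {
  base <- c(nrem_s = 4000, rem_s = 5000, light_s = 12000, waso_s = 2000,
            hr_min = 50, hr_avg = 60, hr_max = 72,
            rr_min = 12, rr_avg = 14, rr_max = 17)
  sdv <- rep(1, 10)
  list(
    phenotype_spec(1L, base, between * sdv, within * sdv,
                   age_mean = 75, age_sd = 5, prob_plwd = 0.7,
                   prob_female = 0.5),
    phenotype_spec(2L, base + sep * c(100, 100, 100, 100, 1, 1, 1, 0.5, 0.5,
                                      0.5),
                   between * sdv, within * sdv,
                   age_mean = 70, age_sd = 5, prob_plwd = 0.3,
                   prob_female = 0.5)
  )
}

tiny_config <- function(n_plwd = 4, n_gp = 4, n_nights = 8, seed = 1,
                        miss = c(0, 0), frac_excl = 0) {
  generator_config(n_plwd = n_plwd, n_gp_pool = n_gp, n_nights = n_nights,
                   phenotype_weights = list(plwd = c(0.7, 0.3),
                                            gp = c(0.3, 0.7)),
                   missing_night_prob_range = miss,
                   frac_excludable = frac_excl, seed = seed)
}

# nightly records for one participant from a plain numeric feature matrix
nights_from_matrix <- function(m, id = "P1", start = as.Date("2022-01-01")) {
  colnames(m) <- sleep_features()
  data.frame(participant_id = id, night_date = start + seq_len(nrow(m)) - 1L,
             m, stringsAsFactors = FALSE)
}

# well-separated gaussian blobs for clustering tests
blob_matrix <- function(n_per, centers, sd = 0.2, seed = 1, p = 2) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    matrix(stats::rnorm(n_per * p, mean = rep(centers[i, ], each = n_per),
                        sd = sd), n_per, p)))
}

# brute-force silhouette: plain double loop over points
oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(x) - x[i, ])^2))
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- mean(di[own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(di[labels == l]), numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# brute-force Calinski-Harabasz straight from the definition
oracle_ch <- function(x, labels) {
  n <- nrow(x); k <- length(unique(labels))
  mu <- colMeans(x)
  bet <- 0; wit <- 0
  for (l in unique(labels)) {
    xi <- x[labels == l, , drop = FALSE]
    bet <- bet + nrow(xi) * sum((colMeans(xi) - mu)^2)
    for (r in seq_len(nrow(xi))) wit <- wit + sum((xi[r, ] - colMeans(xi))^2)
  }
  (bet / (k - 1)) / (wit / (n - k))
}

# brute-force Davies-Bouldin with explicit pairwise loops
oracle_db <- function(x, labels) {
  labs <- unique(labels); k <- length(labs)
  cen <- lapply(labs, function(l) colMeans(x[labels == l, , drop = FALSE]))
  sc <- vapply(seq_len(k), function(j) {
    xi <- x[labels == labs[j], , drop = FALSE]
    mean(vapply(seq_len(nrow(xi)),
                function(r) sqrt(sum((xi[r, ] - cen[[j]])^2)), numeric(1)))
  }, numeric(1))
  tot <- 0
  for (ci in seq_len(k)) {
    worst <- -Inf
    for (cj in seq_len(k)) {
      if (ci == cj) next
      r <- (sc[ci] + sc[cj]) / sqrt(sum((cen[[ci]] - cen[[cj]])^2))
      worst <- max(worst, r)
    }
    tot <- tot + worst
  }
  tot / k
}

# random labelled instance where every cluster has >= 2 members
random_instance <- function(n, k, p = 3, seed) {
  set.seed(seed)
  repeat {
    labels <- sample.int(k, n, replace = TRUE)
    if (all(tabulate(labels, k) >= 2)) break
  }
  list(x = matrix(stats::rnorm(n * p), n, p), labels = labels)
}
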