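#' Correlation distance between two expression profiles
#'
#' `1 - Pearson(u, v)`, in `[0, 2]`: 0 for perfectly correlated profiles,
#' 2 for perfectly anticorrelated ones. Invariant to positive affine
#' rescaling of either profile.
#'
#' @param u,v numeric profiles of equal length >= 3, each with nonzero
#'   variance.
#' @return A single number in `[0, 2]`.
#' @examples
#' x <- rnorm(10)
#' correlation_distance(x, 2 * x + 3)  # 0
#' @export
correlation_distance <- function(u, v) {
  if (length(u) != length(v)) {
    stop("profiles must have equal length", call. = FALSE)
  }
  if (length(u) < 3) {
    stop("profiles must have length >= 3", call. = FALSE)
  }
  if (sd(u) == 0 || sd(v) == 0) {
    stop("zero-variance (constant) profile: correlation distance undefined",
         call. = FALSE)
  }
  1 - cor(u, v)
}

# Row-standardize profiles to zero mean and unit Euclidean norm. On this
# geometry squared Euclidean distance equals 2 * (1 - Pearson), so ordinary
# k-means minimizes the correlation-distance objective.
standardize_profiles <- function(profiles) {
  if (any(apply(profiles, 1, sd) == 0)) {
    bad <- rownames(profiles)[apply(profiles, 1, sd) == 0]
    stop("zero-variance profile(s): ",
         paste(if (is.null(bad)) "<unnamed>" else bad, collapse = ", "),
         call. = FALSE)
  }
  ctr <- profiles - rowMeans(profiles)
  ctr / sqrt(rowSums(ctr^2))
}

#' K-means clustering of profiles under correlation distance
#'
#' Groups signature variables whose expression profiles across samples are
#' highly correlated. Each profile is standardized to zero mean and unit
#' norm, on which squared Euclidean distance equals twice the correlation
#' distance, and ordinary k-means (Lloyd iterations, best of `n_restarts`
#' random starts) is run on the standardized rows. Exactly duplicated
#' profiles are collapsed before clustering and share their representative's
#' assignment, so they are always co-clustered. The cluster count is
#' typically taken from the size of the minimal-mu signature (`k_min` of
#' [mu_path()]), one cluster per correlated group.
#'
#' @param profiles numeric matrix, signature variables in rows, samples in
#'   columns (>= 3 samples); every row must have nonzero variance.
#' @param k number of clusters, at most the number of distinct profiles.
#' @param seed integer seed; the assignment is deterministic given the seed.
#' @param n_restarts random restarts (default 20); the best objective wins.
#' @param max_iter Lloyd iteration cap per restart (default 300).
#' @return An object of class `cluster_assignment`: list with `cluster`
#'   (named integer vector), `k`, `tot_within` (total within-cluster squared
#'   distance on the standardized geometry), `within_mean_distance` (mean
#'   correlation distance to the cluster centroid), `seed`, `n_restarts`.
#' @export
kmeans_correlation <- function(profiles, k, seed = 1, n_restarts = 20,
                               max_iter = 300) {
  profiles <- as.matrix(profiles)
  if (ncol(profiles) < 3) {
    stop("profiles must have at least 3 samples (columns)", call. = FALSE)
  }
  k <- as.integer(k)
  if (k < 1 || k > nrow(profiles)) {
    stop("k must be between 1 and the number of profiles", call. = FALSE)
  }
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- paste0("P", seq_len(nrow(profiles)))
  }
  std <- standardize_profiles(profiles)
  key <- apply(round(std, 12), 1, paste, collapse = ",")
  uniq_idx <- which(!duplicated(key))
  uniq <- std[uniq_idx, , drop = FALSE]
  if (k > nrow(uniq)) {
    stop(sprintf("k = %d exceeds the number of distinct profiles (%d)",
                 k, nrow(uniq)), call. = FALSE)
  }
  if (k == nrow(uniq)) {
    # singleton clusters: objective is exactly 0, no iteration needed
    uniq_cluster <- seq_len(nrow(uniq))
    tot_within <- 0
  } else {
    # individual random restarts may hit an empty cluster or the iteration
    # cap; those notes concern discarded starts, so only the winning
    # partition is checked below
    km <- with_seed(seed, suppressWarnings(
      kmeans(uniq, centers = k, nstart = n_restarts, iter.max = max_iter,
             algorithm = "Lloyd")))
    uniq_cluster <- km$cluster
    tot_within <- km$tot.withinss
    if (length(unique(uniq_cluster)) < k) {
      warning(sprintf("only %d of %d clusters are nonempty",
                      length(unique(uniq_cluster)), k), call. = FALSE)
    }
  }
  cluster <- uniq_cluster[match(key, key[uniq_idx])]
  names(cluster) <- rownames(profiles)
  # mean correlation distance to centroid: d_cor = ||x - c||^2 / 2 on the
  # standardized geometry, averaged over profiles
  centroids <- do.call(rbind, lapply(seq_len(k), function(g) {
    colMeans(std[cluster == g, , drop = FALSE])
  }))
  wd <- mean(rowSums((std - centroids[cluster, , drop = FALSE])^2) / 2)
  structure(
    list(cluster = cluster, k = k, tot_within = tot_within,
         within_mean_distance = wd, seed = seed, n_restarts = n_restarts),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat(sprintf(
    "cluster_assignment: %d profiles in %d clusters (mean within-distance %.4f)\n",
    length(x$cluster), x$k, x$within_mean_distance))
  print(split(names(x$cluster), x$cluster))
  invisible(x)
}

#' Min-max scale profiles to [0, 1] per variable
#'
#' Visualization helper for heatmaps of clustered signatures: rescales each
#' profile linearly so its minimum maps to 0 and its maximum to 1.
#'
#' @param profiles numeric matrix, variables in rows.
#' @return Matrix of the same shape with rows in `[0, 1]`.
#' @export
scale01 <- function(profiles) {
  rng <- apply(profiles, 1, range)
  span <- rng[2, ] - rng[1, ]
  if (any(span == 0)) {
    stop("constant profile cannot be min-max scaled", call. = FALSE)
  }
  (profiles - rng[1, ]) / span
}
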