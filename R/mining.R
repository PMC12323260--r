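#' Pairwise-distance featurization of a conformer ensemble
#'
#' Flattens the upper triangle of each conformer's pairwise distance matrix
#' into a feature vector of length `m = n(n-1)/2`, the representation on
#' which conformer clustering and constraint mining operate. Columns follow
#' row-major upper-triangle order: (1,2), (1,3), ..., (1,n), (2,3), ...
#'
#' @param ensemble list of [conformation()]s with identical atom counts.
#' @return a `distance_features` object: list with `vectors` (`C x m`
#'   matrix), `pair_index` (data frame with columns `i`, `j`), `n_atoms`.
#' @examples
#' tri <- conformation(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
#' featurize_distances(list(tri))$vectors # 1, 1, sqrt(2)
#' @export
featurize_distances <- function(ensemble) {
  stopifnot(length(ensemble) >= 1L)
  ensemble <- lapply(ensemble, as_conformation)
  n <- ensemble[[1L]]$n_atoms
  if (!all(vapply(ensemble, `[[`, 0L, "n_atoms") == n)) {
    stop("all conformers must have the same atom count", call. = FALSE)
  }
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
  vecs <- t(vapply(ensemble, function(cf) {
    D <- as.matrix(stats::dist(cf$coordinates))
    D[cbind(pairs[, 1L], pairs[, 2L])]
  }, numeric(nrow(pairs))))
  structure(
    list(vectors = vecs,
         pair_index = data.frame(i = pairs[, 1L], j = pairs[, 2L]),
         n_atoms = n),
    class = "distance_features")
}

#' Cluster conformers by their distance features
#'
#' k-means (k-means++-style multiple restarts via `nstart`) on the flattened
#' pairwise-distance vectors, partitioning the ensemble into geometric
#' modes.
#'
#' @param features a [featurize_distances()] result.
#' @param n_clusters number of clusters.
#' @param seed integer seed (clustering is deterministic given the seed).
#' @param nstart random restarts (default 10).
#' @return integer vector of cluster labels (1-based), length `C`.
#' @export
cluster_conformers <- function(features, n_clusters, seed = 1L,
                               nstart = 10L) {
  stopifnot(inherits(features, "distance_features"))
  C <- nrow(features$vectors)
  if (n_clusters < 1L) stop("n_clusters must be at least 1", call. = FALSE)
  if (n_clusters > C) stop("more clusters than conformers", call. = FALSE)
  if (n_clusters == 1L) return(rep(1L, C))
  set.seed(seed)
  km <- stats::kmeans(features$vectors, centers = n_clusters,
                      nstart = nstart, iter.max = 100L)
  as.integer(km$cluster)
}

#' Cluster-vs-global significance of atom pairs
#'
#' For each cluster `k` and atom pair `(i, j)`, the significance is the
#' absolute deviation of the cluster-mean distance from the global-mean
#' distance, `Delta_k(i,j) = |xbar_k(i,j) - xbar(i,j)|`. Pairs with large
#' `Delta` are the distances that distinguish the cluster's geometry from
#' the ensemble average -- the natural candidates for cluster-specific
#' constraints.
#'
#' @param features a [featurize_distances()] result.
#' @param labels integer cluster labels (1-based) from
#'   [cluster_conformers()].
#' @return a `cluster_constraint_report`: list with `labels`,
#'   `cluster_means` (`K x m`), `global_mean` (length `m`), `significance`
#'   (`K x m` matrix of `Delta`), `pair_index`, `cluster_sd` (`K x m`
#'   within-cluster standard deviations).
#' @export
constraint_significance <- function(features, labels) {
  stopifnot(inherits(features, "distance_features"))
  labels <- as.integer(labels)
  C <- nrow(features$vectors)
  if (length(labels) != C) stop("labels length mismatch", call. = FALSE)
  K <- max(labels)
  if (!all(seq_len(K) %in% labels)) {
    empty <- setdiff(seq_len(K), unique(labels))
    stop(sprintf("empty cluster: %s", paste(empty, collapse = ", ")),
         call. = FALSE)
  }
  global_mean <- colMeans(features$vectors)
  cluster_means <- matrix(0, nrow = K, ncol = ncol(features$vectors))
  cluster_sd <- matrix(0, nrow = K, ncol = ncol(features$vectors))
  for (k in seq_len(K)) {
    sub <- features$vectors[labels == k, , drop = FALSE]
    cluster_means[k, ] <- colMeans(sub)
    cluster_sd[k, ] <- apply(sub, 2L, stats::sd)
  }
  cluster_sd[is.na(cluster_sd)] <- 0   # singleton clusters
  delta <- abs(sweep(cluster_means, 2L, global_mean))
  structure(
    list(labels = labels, cluster_means = cluster_means,
         global_mean = global_mean, significance = delta,
         pair_index = features$pair_index, cluster_sd = cluster_sd),
    class = "cluster_constraint_report")
}

#' Top-T mined constraints for a cluster
#'
#' Selects the `T` atom pairs with the highest significance `Delta_k` for
#' the requested cluster (ties broken lexicographically by pair index) and
#' turns them into distance constraints targeting the cluster-mean
#' distances. With `bounded = TRUE` the constraints carry the interval
#' `[xbar_k - sd_k, xbar_k + sd_k]` (within-cluster standard deviation) as
#' final bounds instead of a strict equality.
#'
#' @param report a [constraint_significance()] result.
#' @param top_t number of constraints to mine (at most `m`).
#' @param cluster cluster id (1-based).
#' @param bounded emit bounded constraints from the within-cluster spread
#'   (default `FALSE` = strict equality at the cluster mean).
#' @param schedule optional [bound_schedule()] template attached to every
#'   mined constraint (its final bounds are replaced per constraint).
#' @return a [constraint_set()] of `top_t` distance constraints, ordered by
#'   decreasing significance.
#' @export
top_constraints <- function(report, top_t, cluster, bounded = FALSE,
                            schedule = NULL) {
  stopifnot(inherits(report, "cluster_constraint_report"))
  K <- nrow(report$cluster_means)
  if (cluster < 1L || cluster > K) stop("invalid cluster id", call. = FALSE)
  m <- ncol(report$significance)
  if (top_t < 1L || top_t > m) stop("top_t must be in 1..m", call. = FALSE)
  delta <- report$significance[cluster, ]
  ord <- order(-delta, report$pair_index$i, report$pair_index$j)
  sel <- ord[seq_len(top_t)]
  constraint_set(lapply(sel, function(col) {
    i <- report$pair_index$i[col]
    j <- report$pair_index$j[col]
    target <- report$cluster_means[cluster, col]
    sch <- if (!is.null(schedule)) {
      lf <- if (bounded) target - report$cluster_sd[cluster, col] else target
      uf <- if (bounded) target + report$cluster_sd[cluster, col] else target
      bound_schedule(beta = schedule$beta, t0 = schedule$t0,
                     lower_initial = schedule$lower_initial,
                     upper_initial = schedule$upper_initial,
                     lower_final = lf, upper_final = uf,
                     unbounded_width = schedule$unbounded_width)
    } else NULL
    if (bounded) {
      distance_constraint(i, j, target,
                          lower_final = target -
                            report$cluster_sd[cluster, col],
                          upper_final = target +
                            report$cluster_sd[cluster, col],
                          schedule = sch)
    } else {
      distance_constraint(i, j, target, schedule = sch)
    }
  }))
}

#' PCA loadings over pairwise distances
#'
#' Principal component analysis of the mean-centered distance features. For
#' each component, atom pairs are ranked by absolute loading (their
#' contribution to that axis of conformational variance) and the conformer
#' with the most extreme score is reported as the component's
#' representative.
#'
#' @param features a [featurize_distances()] result.
#' @param n_components number of components to report.
#' @param top_t number of top-loading pairs to list per component.
#' @return list with `loadings` (`m x n_components`), `scores`
#'   (`C x n_components`), `explained_variance`, and `components`: one
#'   entry per component holding `pairs` (data frame `i`, `j`,
#'   `loading`, ordered by `|loading|` descending) and
#'   `representative_conformer` (index of the extreme-score conformer).
#' @export
pca_constraint_loadings <- function(features, n_components = 3L,
                                    top_t = 5L) {
  stopifnot(inherits(features, "distance_features"))
  X <- features$vectors
  n_components <- min(n_components, nrow(X) - 1L, ncol(X))
  if (n_components < 1L) stop("not enough data for PCA", call. = FALSE)
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  rank_ <- sum(pc$sdev > 1e-12 * pc$sdev[1L])
  comps <- lapply(seq_len(n_components), function(q) {
    load <- pc$rotation[, q]
    ord <- order(-abs(load), features$pair_index$i, features$pair_index$j)
    sel <- ord[seq_len(min(top_t, length(ord)))]
    list(pairs = data.frame(i = features$pair_index$i[sel],
                            j = features$pair_index$j[sel],
                            loading = load[sel]),
         representative_conformer = which.max(abs(pc$x[, q])),
         degenerate = q > rank_)
  })
  list(loadings = pc$rotation[, seq_len(n_components), drop = FALSE],
       scores = pc$x[, seq_len(n_components), drop = FALSE],
       explained_variance = pc$sdev[seq_len(n_components)]^2,
       components = comps)
}

#' Silhouette-based cluster-count helper
#'
#' Convenience only (not part of the mining procedure itself): mean
#' silhouette width over a range of k, computed from Euclidean distances in
#' feature space.
#'
#' @param features a [featurize_distances()] result.
#' @param k_range candidate cluster counts (default 2:6).
#' @param seed integer seed.
#' @return data frame with `k` and `mean_silhouette`.
#' @export
suggest_n_clusters <- function(features, k_range = 2:6, seed = 1L) {
  D <- as.matrix(stats::dist(features$vectors))
  res <- vapply(k_range, function(k) {
    labels <- cluster_conformers(features, k, seed = seed)
    sil <- vapply(seq_along(labels), function(c) {
      own <- labels[c]
      a <- mean(D[c, labels == own & seq_along(labels) != c])
      if (is.nan(a)) return(0)
      b <- min(vapply(setdiff(unique(labels), own), function(o)
        mean(D[c, labels == o]), numeric(1)))
      (b - a) / max(a, b)
    }, numeric(1))
    mean(sil)
  }, numeric(1))
  data.frame(k = k_range, mean_silhouette = res)
}
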