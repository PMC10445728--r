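#' @title Temporal fold-change clustering with internal validity indices
#'
#' @description
#' Groups differentially enriched proteins by their per-time-point log2
#' fold-change profiles with k-means (Euclidean distance, multiple random
#' restarts), and selects the number of clusters by internal validity:
#' mean silhouette width, Dunn index and connectivity are computed for every
#' candidate k on the same distance as the clustering, with the
#' silhouette-optimal k chosen by default (the full table is always
#' reported).
#'
#' @name temporal_cluster
NULL

#' Build the fold-change profile matrix for clustering
#'
#' @param rows output of [moderated_t()].
#' @param proteins proteins to keep (default: the [call_significant()] union).
#' @return numeric matrix proteins x contrasts of log2 fold changes.
#' @export
fc_profile_matrix <- function(rows, proteins = NULL) {
  if (is.null(proteins)) proteins <- call_significant(rows)$union
  contrasts <- unique(rows$contrast)
  out <- sapply(contrasts, function(cc) {
    sub <- rows[rows$contrast == cc, ]
    sub$log2fc[match(proteins, sub$protein_id)]
  })
  out <- matrix(out, nrow = length(proteins),
                dimnames = list(proteins, contrasts))
  out
}

#' k-means clustering of fold-change profiles
#'
#' Best of `n_restarts` random starts by within-cluster sum of squares;
#' deterministic given `seed`.
#'
#' @param fc numeric matrix (proteins x time points), no missing values.
#' @param k number of clusters; must not exceed the number of rows.
#' @param seed integer RNG seed.
#' @param n_restarts random restarts (default 25).
#' @return list of class `cluster_result`: `cluster` (named assignment
#'   vector), `centroids` (k x T matrix), `k`, `seed`, `objective` (WCSS).
#' @export
kmeans_profiles <- function(fc, k, seed = 1L, n_restarts = 25L) {
  fc <- as.matrix(fc)
  if (anyNA(fc)) stop("fold-change matrix contains missing values")
  if (k > nrow(fc)) stop("k (", k, ") exceeds number of proteins (",
                         nrow(fc), ")")
  if (k == nrow(fc)) {
    # singleton partition: every profile its own cluster
    return(structure(list(cluster = stats::setNames(seq_len(k), rownames(fc)),
                          centroids = fc, k = k, seed = seed, objective = 0),
                     class = "cluster_result"))
  }
  set.seed(seed)
  km <- stats::kmeans(fc, centers = k, nstart = n_restarts, iter.max = 100L)
  structure(list(cluster = stats::setNames(km$cluster, rownames(fc)),
                 centroids = km$centers, k = k, seed = seed,
                 objective = km$tot.withinss),
            class = "cluster_result")
}

#' Mean silhouette width of a partition
#'
#' @param fc data matrix; Euclidean distance is used.
#' @param cluster integer assignment vector.
#' @return mean silhouette width in \[-1, 1\].
#' @export
silhouette_index <- function(fc, cluster) {
  if (length(unique(cluster)) < 2) stop("silhouette needs >= 2 clusters")
  sil <- cluster::silhouette(as.integer(factor(cluster)),
                             dist = stats::dist(fc))
  mean(sil[, "sil_width"])
}

#' Dunn index of a partition
#'
#' Minimum between-cluster point-to-point distance divided by the maximum
#' cluster diameter (both Euclidean). Larger is better; positive for
#' non-degenerate partitions.
#'
#' @inheritParams silhouette_index
#' @export
dunn_index <- function(fc, cluster) {
  d <- as.matrix(stats::dist(fc))
  cl <- as.integer(factor(cluster))
  same <- outer(cl, cl, "==")
  off_diag <- !diag(nrow(d))
  within <- d[same & off_diag]
  between <- d[!same]
  if (!length(between)) stop("Dunn index needs >= 2 clusters")
  max_diam <- if (length(within)) max(within) else 0
  if (max_diam == 0) stop("degenerate partition: zero within-cluster spread")
  min(between) / max_diam
}

#' Connectivity of a partition
#'
#' For each point, its `n_neighbors` nearest neighbours (Euclidean) are
#' inspected; a neighbour in a different cluster adds `1/rank` to the score.
#' Lower is better; 0 means every point's nearest neighbours share its
#' cluster.
#'
#' @inheritParams silhouette_index
#' @param n_neighbors neighbourhood size (default 2).
#' @export
connectivity_index <- function(fc, cluster, n_neighbors = 2L) {
  d <- as.matrix(stats::dist(fc))
  diag(d) <- Inf
  cl <- as.integer(factor(cluster))
  total <- 0
  for (i in seq_len(nrow(d))) {
    nn <- order(d[i, ])[seq_len(n_neighbors)]
    viol <- cl[nn] != cl[i]
    total <- total + sum((1 / seq_len(n_neighbors))[viol])
  }
  total
}

#' Select the number of clusters by internal validity
#'
#' Runs [kmeans_profiles()] for each candidate k and computes the mean
#' silhouette width, Dunn index and connectivity on the resulting partition.
#' `k_star` is the silhouette-optimal k; the full table is returned so the
#' three indices can be weighed by eye (they need not agree).
#'
#' @param fc numeric matrix (proteins x time points).
#' @param k_range candidate cluster counts (default `2:30`, truncated to
#'   `nrow(fc) - 1`).
#' @param seed integer RNG seed.
#' @param n_restarts restarts per k (default 25).
#' @param n_neighbors connectivity neighbourhood size (default 2).
#' @return list with `k_star` and `validity` (a `data.frame` with columns
#'   `k`, `silhouette`, `dunn`, `connectivity`).
#' @export
select_k <- function(fc, k_range = 2:30, seed = 1L, n_restarts = 25L,
                     n_neighbors = 2L) {
  fc <- as.matrix(fc)
  if (nrow(unique(fc)) < 2) {
    stop("degenerate input: all profiles identical")
  }
  k_range <- k_range[k_range >= 2 & k_range <= nrow(unique(fc)) - 1]
  if (!length(k_range)) stop("no admissible k in k_range")
  validity <- do.call(rbind, lapply(k_range, function(k) {
    res <- kmeans_profiles(fc, k, seed = seed, n_restarts = n_restarts)
    data.frame(k = k,
               silhouette = silhouette_index(fc, res$cluster),
               dunn = dunn_index(fc, res$cluster),
               connectivity = connectivity_index(fc, res$cluster,
                                                 n_neighbors = n_neighbors))
  }))
  list(k_star = validity$k[which.max(validity$silhouette)],
       validity = validity)
}
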