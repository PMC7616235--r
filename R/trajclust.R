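#' Multivariate dynamic time warping distance between two trajectories
#'
#' Dependent multivariate DTW: the local cost between grid points is the
#' Euclidean distance over all shared dimensions; the classic dynamic program
#' over the L_a x L_b lattice with steps (i-1,j), (i,j-1), (i-1,j-1) returns
#' the accumulated cost of the optimal monotone warping path. Note DTW is
#' symmetric and non-negative with d(a,a)=0 but does not satisfy the triangle
#' inequality.
#'
#' @param traj_a,traj_b `clone_trajectory` objects or plain L x D matrices
#'   (equal D required; a univariate series may be a vector).
#' @return Non-negative accumulated cost.
#' @export
dtw_distance <- function(traj_a, traj_b) {
  a <- as_grid(traj_a); b <- as_grid(traj_b)
  if (ncol(a) != ncol(b)) stop("trajectory dimension mismatch", call. = FALSE)
  if (nrow(a) < 2 || nrow(b) < 2) stop("grids must have length >= 2", call. = FALSE)
  local <- local_cost(a, b)
  la <- nrow(a); lb <- nrow(b)
  acc <- matrix(Inf, la, lb)
  acc[1, 1] <- local[1, 1]
  for (j in 2:lb) acc[1, j] <- acc[1, j - 1] + local[1, j]
  for (i in 2:la) {
    acc[i, 1] <- acc[i - 1, 1] + local[i, 1]
    for (j in 2:lb) {
      acc[i, j] <- local[i, j] +
        min(acc[i - 1, j], acc[i, j - 1], acc[i - 1, j - 1])
    }
  }
  acc[la, lb]
}

as_grid <- function(x) {
  if (inherits(x, "clone_trajectory")) x <- x$grid
  if (is.null(dim(x))) x <- matrix(x, ncol = 1)
  as.matrix(x)
}

# column-by-column squared differences: exact (identical rows give 0),
# no cancellation from the outer-product expansion
local_cost <- function(a, b) {
  ta <- t(a)
  vapply(seq_len(nrow(b)), function(j) {
    sqrt(colSums((ta - b[j, ])^2))
  }, numeric(nrow(a)))
}

#' Pairwise distance matrix over clone trajectories
#'
#' @param trajectories a `trajectory_set` (named list of trajectories).
#' @param metric `"dtw"` (multivariate DTW) or `"euclidean_flat"` (grids
#'   flattened to vectors, Euclidean — a fast ablation that ignores warping).
#' @return Symmetric matrix with zero diagonal, clone-id dimnames and a
#'   `"metric"` attribute.
#' @export
build_distance_matrix <- function(trajectories, metric = c("dtw", "euclidean_flat")) {
  metric <- match.arg(metric)
  n <- length(trajectories)
  if (n < 2) stop("need at least 2 trajectories", call. = FALSE)
  ids <- names(trajectories)
  if (is.null(ids)) ids <- vapply(trajectories, function(t) t$clone_id, character(1))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (metric == "euclidean_flat") {
    flat <- t(vapply(trajectories, function(t) as.vector(as_grid(t)),
                     numeric(length(as_grid(trajectories[[1]])))))
    d <- as.matrix(stats::dist(flat))
    dimnames(d) <- list(ids, ids)
  } else {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- dtw_distance(trajectories[[i]], trajectories[[j]])
      }
    }
  }
  attr(d, "metric") <- metric
  d
}

#' Flag outlier clones from a distance matrix
#'
#' A clone is an outlier when its median distance to all other clones exceeds
#' Q3 + 1.5 IQR of those per-clone medians (the usual boxplot fence); ids in
#' `manual` are always excluded.
#'
#' @param distance_matrix symmetric distance matrix with clone-id dimnames.
#' @param rule only `"iqr"` is implemented.
#' @param manual clone ids to exclude unconditionally.
#' @return List with `kept` and `excluded` clone-id vectors.
#' @export
detect_outliers <- function(distance_matrix, rule = "iqr", manual = character()) {
  ids <- rownames(distance_matrix)
  bad_manual <- setdiff(manual, ids)
  if (length(bad_manual)) {
    stop("manual outlier id(s) not present: ",
         paste(bad_manual, collapse = ", "), call. = FALSE)
  }
  excluded <- character()
  if (identical(rule, "iqr")) {
    n <- nrow(distance_matrix)
    if (n < 3) stop("iqr rule needs at least 3 clones", call. = FALSE)
    med <- vapply(seq_len(n), function(i) {
      stats::median(distance_matrix[i, -i])
    }, numeric(1))
    q <- stats::quantile(med, c(0.25, 0.75), names = FALSE)
    fence <- q[2] + 1.5 * (q[2] - q[1])
    excluded <- ids[med > fence]
  } else if (!is.null(rule)) {
    stop("unknown outlier rule '", rule, "'", call. = FALSE)
  }
  excluded <- union(excluded, manual)
  list(kept = setdiff(ids, excluded), excluded = excluded)
}

#' Average-linkage hierarchical clustering on a precomputed distance matrix
#'
#' Thin deterministic wrapper around `stats::hclust`; average linkage is the
#' default because the trajectory distances are non-Euclidean.
#'
#' @param distance_matrix symmetric finite distance matrix.
#' @param linkage linkage method passed to `hclust`.
#' @return An `hclust` merge tree.
#' @export
hierarchical_cluster <- function(distance_matrix, linkage = "average") {
  if (any(!is.finite(distance_matrix))) {
    stop("non-finite distances", call. = FALSE)
  }
  stats::hclust(stats::as.dist(distance_matrix), method = linkage)
}

#' Mean silhouette of a labelling under a precomputed distance matrix
#'
#' s(i) = (b - a) / max(a, b) with a(i) the mean intra-cluster distance
#' (excluding self) and b(i) the smallest mean distance to another cluster;
#' singletons get s = 0.
#'
#' @param labels cluster labels over the distance-matrix rows.
#' @param distance_matrix symmetric distance matrix.
#' @return Mean silhouette over items.
#' @export
silhouette_score <- function(labels, distance_matrix) {
  labels <- as.integer(factor(labels))
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- sum(distance_matrix[i, own]) / (length(own) - 1)
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(l) {
      mean(distance_matrix[i, labels == l])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Cut a merge tree at the silhouette-maximizing number of clusters
#'
#' Evaluates every K in `[k_min, k_max]` by cutting the tree and scoring the
#' partition with [silhouette_score()] on the precomputed distances; the K
#' with the highest mean silhouette wins, ties going to the smaller K
#' (parsimony).
#'
#' @param tree `hclust` tree from [hierarchical_cluster()].
#' @param distance_matrix the distance matrix the tree was built on.
#' @param k_min,k_max candidate range (`k_min >= 2`; `k_max` is capped at
#'   n - 1).
#' @return A `traj_clusters` object: `assignment` tibble (`clone_id`,
#'   `cluster`), `K`, `tree`, `silhouette_by_k` tibble, `excluded_outliers`.
#' @export
flatten_by_silhouette <- function(tree, distance_matrix, k_min = 2, k_max = 10) {
  if (k_min < 2) stop("k_min must be >= 2", call. = FALSE)
  n <- nrow(distance_matrix)
  k_max <- min(k_max, n - 1)
  ks <- k_min:k_max
  sil <- vapply(ks, function(k) {
    silhouette_score(stats::cutree(tree, k = k), distance_matrix)
  }, numeric(1))
  K <- ks[which.max(sil)]          # which.max takes the first (smallest) tie
  labels <- stats::cutree(tree, k = K)
  structure(list(
    assignment = tibble::tibble(clone_id = rownames(distance_matrix),
                                cluster = as.integer(labels)),
    K = K,
    tree = tree,
    silhouette_by_k = tibble::tibble(k = ks, mean_silhouette = sil),
    excluded_outliers = character()
  ), class = "traj_clusters")
}

#' @exportS3Method base::print
print.traj_clusters <- function(x, ...) {
  cat("<traj_clusters> K = ", x$K, " over ", nrow(x$assignment), " clones",
      sep = "")
  if (length(x$excluded_outliers)) {
    cat(" (", length(x$excluded_outliers), " outlier(s) excluded)", sep = "")
  }
  cat("\n  cluster sizes:",
      paste(table(x$assignment$cluster), collapse = ", "), "\n")
  invisible(x)
}

#' Cluster clones by trajectory similarity
#'
#' The full procedure: pairwise multivariate DTW distances between per-clone
#' trajectories, IQR-fence outlier removal, average-linkage hierarchical
#' clustering, and silhouette-maximizing selection of the cluster number.
#'
#' @param trajectories a `trajectory_set` from [build_clone_trajectories()].
#' @param metric distance metric, see [build_distance_matrix()].
#' @param outlier_rule `"iqr"` or `NULL` to skip outlier removal.
#' @param manual_outliers clone ids excluded unconditionally.
#' @param linkage hclust linkage.
#' @param k_min,k_max candidate cluster-number range.
#' @return A `traj_clusters` object with `distance_matrix` attached.
#' @export
cluster_trajectories <- function(trajectories, metric = "dtw",
                                 outlier_rule = "iqr",
                                 manual_outliers = character(),
                                 linkage = "average", k_min = 2, k_max = 10) {
  d <- build_distance_matrix(trajectories, metric)
  excluded <- character()
  if (!is.null(outlier_rule) || length(manual_outliers)) {
    out <- detect_outliers(d, rule = outlier_rule, manual = manual_outliers)
    excluded <- out$excluded
    if (length(out$kept) < 3) stop("fewer than 3 clones after outlier removal",
                                   call. = FALSE)
    d <- d[out$kept, out$kept]
  }
  tree <- hierarchical_cluster(d, linkage)
  res <- flatten_by_silhouette(tree, d, k_min, k_max)
  res$excluded_outliers <- excluded
  res$distance_matrix <- d
  res
}

#' Centroid-based baseline clone clustering in a 2-D embedding
#'
#' The established first-moment comparator: each clone is represented by the
#' centroid of its cells in a provided 2-D embedding (e.g. UMAP coordinates
#' computed elsewhere, or the first two PCs); clones are then clustered with
#' exactly the same machinery (Euclidean distances, average linkage,
#' silhouette-selected K). Because it only sees first moments, it cannot
#' separate patterns that share a centroid.
#'
#' @param clones clone tibble (>= 2 rows).
#' @param embedding_2d matrix of per-cell coordinates with barcode rownames
#'   (first two columns used) or a `cell_embedding`.
#' @param k_min,k_max candidate cluster-number range.
#' @param linkage hclust linkage.
#' @return A `traj_clusters` object.
#' @export
baseline_centroid_cluster <- function(clones, embedding_2d, k_min = 2,
                                      k_max = 10, linkage = "average") {
  if (nrow(clones) < 2) stop("need at least 2 clones", call. = FALSE)
  coords <- embedding_coords(embedding_2d)
  if (ncol(coords) < 2) stop("embedding must have >= 2 dimensions", call. = FALSE)
  coords <- coords[, 1:2, drop = FALSE]
  cent <- t(vapply(clones$barcodes, function(bc) {
    if (!all(bc %in% rownames(coords))) {
      stop("missing coordinates for some member cells", call. = FALSE)
    }
    colMeans(coords[bc, , drop = FALSE])
  }, numeric(2)))
  rownames(cent) <- clones$clone_id
  d <- as.matrix(stats::dist(cent))
  attr(d, "metric") <- "centroid_euclidean"
  tree <- hierarchical_cluster(d, linkage)
  res <- flatten_by_silhouette(tree, d, k_min, k_max)
  res$distance_matrix <- d
  res
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected pair-counting agreement; 1 for identical partitions
#' (up to label renaming), ~0 for independent ones.
#'
#' @param labels_a,labels_b label vectors over the same items.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(labels_a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
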