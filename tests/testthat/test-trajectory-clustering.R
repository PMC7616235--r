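test_that("DTW distance is zero on identity, symmetric, non-negative", {
  trajs <- random_trajectories(6, L = 5, D = 3, seed = 2)
  for (tr in trajs) expect_equal(dtw_distance(tr, tr), 0)
  for (i in 1:5) {
    a <- trajs[[i]]; b <- trajs[[i + 1]]
    d <- dtw_distance(a, b)
    expect_gte(d, 0)
    expect_equal(d, dtw_distance(b, a))
  }
  expect_error(dtw_distance(matrix(0, 4, 2), matrix(0, 4, 3)), "mismatch")
  expect_error(dtw_distance(matrix(0, 1, 2), matrix(0, 4, 2)), "length")
})

test_that("DTW equals brute-force warping-path enumeration on small grids", {
  # a small hand-checkable univariate pair
  expect_equal(dtw_distance(c(0, 1, 2, 3), c(0, 2, 2, 3)),
               dtw_brute(c(0, 1, 2, 3), c(0, 2, 2, 3)))
  set.seed(10)
  for (i in 1:25) {
    la <- sample(2:6, 1); lb <- sample(2:6, 1); d <- sample(1:3, 1)
    a <- matrix(rnorm(la * d), la, d)
    b <- matrix(rnorm(lb * d), lb, d)
    expect_equal(dtw_distance(a, b), dtw_brute(a, b), tolerance = 1e-12)
  }
})

test_that("distance matrices are symmetric, zero-diagonal and faithful", {
  trajs <- random_trajectories(5, L = 6, D = 2, seed = 3)
  d <- build_distance_matrix(trajs)
  expect_equal(d, t(d), ignore_attr = TRUE)
  expect_equal(unname(diag(d)), rep(0, 5))
  expect_equal(d["c02", "c04"], dtw_distance(trajs[[2]], trajs[[4]]))
  expect_equal(d["c01", "c05"], dtw_distance(trajs[[1]], trajs[[5]]))
  # identical trajectories give an all-zero matrix
  same <- trajs[c(1, 1, 1)]
  names(same) <- c("x", "y", "z"); class(same) <- "trajectory_set"
  expect_equal(max(build_distance_matrix(same)), 0)
  expect_error(build_distance_matrix(trajs[1]), "at least 2")
  # euclidean_flat agrees with flattening by hand
  df <- build_distance_matrix(trajs, metric = "euclidean_flat")
  flat <- sapply(trajs, function(t) as.vector(t$grid))
  expect_equal(df["c01", "c03"], sqrt(sum((flat[, 1] - flat[, 3])^2)))
})

test_that("the IQR fence flags distant clones and manual ids", {
  # tight cluster plus one point far away
  set.seed(5)
  pts <- rbind(matrix(rnorm(18, sd = 0.1), 9, 2), c(100, 100))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("c%d", 1:10), sprintf("c%d", 1:10))
  out <- detect_outliers(d)
  expect_equal(out$excluded, "c10")
  expect_length(out$kept, 9)
  # homogeneous cloud: nothing excluded, fence matches direct quantiles
  set.seed(6)
  pts2 <- matrix(runif(40), 20, 2)
  d2 <- as.matrix(dist(pts2))
  dimnames(d2) <- list(sprintf("c%d", 1:20), sprintf("c%d", 1:20))
  med <- sapply(1:20, function(i) median(d2[i, -i]))
  fence <- quantile(med, 0.75) + 1.5 * diff(quantile(med, c(0.25, 0.75)))
  expect_equal(detect_outliers(d2)$excluded,
               rownames(d2)[med > fence], ignore_attr = TRUE)
  expect_length(detect_outliers(d2)$excluded, 0)
  # manual exclusion always applies; unknown ids are an error
  expect_true("c7" %in% detect_outliers(d2, manual = "c7")$excluded)
  expect_error(detect_outliers(d2, manual = "zz"), "not present")
  expect_error(detect_outliers(d2[1:2, 1:2]), "at least 3")
})

test_that("average-linkage trees merge well-separated pairs first", {
  pts <- rbind(c(0, 0), c(0, 0.1), c(10, 10), c(10, 10.1))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(paste0("c", 1:4), paste0("c", 1:4))
  tree <- hierarchical_cluster(d)
  first_two <- tree$merge[1:2, ]
  expect_setequal(as.vector(first_two), c(-1, -2, -3, -4))
  # hand-computed average-linkage oracle, n = 4:
  # d(12)=1, d(34)=1.5, cross distances 6,7,8,9
  dm <- matrix(c(0, 1, 6, 7,
                 1, 0, 8, 9,
                 6, 8, 0, 1.5,
                 7, 9, 1.5, 0), 4, 4,
               dimnames = list(paste0("c", 1:4), paste0("c", 1:4)))
  tr <- hierarchical_cluster(dm)
  expect_equal(tr$height, c(1, 1.5, mean(c(6, 7, 8, 9))))
  d_bad <- dm; d_bad[1, 2] <- d_bad[2, 1] <- Inf
  expect_error(hierarchical_cluster(d_bad), "finite")
})

test_that("the silhouette matches the reference implementation", {
  skip_if_not_installed("cluster")
  set.seed(7)
  pts <- matrix(rnorm(60), 30, 2)
  d <- as.matrix(dist(pts))
  for (k in 2:5) {
    lab <- cutree(hclust(as.dist(d), "average"), k = k)
    ref <- mean(cluster::silhouette(lab, dmatrix = d)[, "sil_width"])
    expect_equal(silhouette_score(lab, d), ref, tolerance = 1e-12)
  }
})

test_that("silhouette flattening picks the best K, ties to smaller K", {
  # two tight far-apart blobs of 5 clones each -> K = 2, silhouette > 0.9
  set.seed(8)
  pts <- rbind(matrix(rnorm(10, sd = 0.05), 5, 2),
               matrix(rnorm(10, sd = 0.05) + 50, 5, 2))
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("c%02d", 1:10), sprintf("c%02d", 1:10))
  res <- flatten_by_silhouette(hierarchical_cluster(d), d)
  expect_equal(res$K, 2)
  expect_gt(glance(res)$mean_silhouette, 0.9)
  expect_equal(sort(unique(tidy(res)$cluster)), 1:2)
  expect_error(flatten_by_silhouette(hierarchical_cluster(d), d, k_min = 1),
               "k_min")
  # selected K equals exhaustive search with the reference silhouette
  skip_if_not_installed("cluster")
  for (seed in 1:10) {
    set.seed(seed)
    p <- matrix(rnorm(32), 8, 4)
    dd <- as.matrix(dist(p))
    dimnames(dd) <- list(sprintf("c%d", 1:8), sprintf("c%d", 1:8))
    tree <- hierarchical_cluster(dd)
    got <- flatten_by_silhouette(tree, dd, k_min = 2, k_max = 6)
    expect_equal(got$K, best_k_exhaustive(tree, dd, 2, 6))
  }
})

test_that("flattening at fixed K is invariant to clone order", {
  set.seed(9)
  pts <- matrix(rnorm(24), 12, 2)
  d <- as.matrix(dist(pts))
  ids <- sprintf("c%02d", 1:12)
  dimnames(d) <- list(ids, ids)
  res <- flatten_by_silhouette(hierarchical_cluster(d), d)
  perm <- sample(12)
  dp <- d[perm, perm]
  resp <- flatten_by_silhouette(hierarchical_cluster(dp), dp)
  expect_equal(resp$K, res$K)
  a <- setNames(res$assignment$cluster, res$assignment$clone_id)
  b <- setNames(resp$assignment$cluster, resp$assignment$clone_id)
  expect_equal(adjusted_rand_index(a[ids], b[ids]), 1)
})

test_that("centroid baseline separates disjoint regions but needs 2+ clones", {
  set.seed(40)
  coords <- rbind(matrix(rnorm(40, sd = 0.2), 20, 2),
                  matrix(rnorm(40, sd = 0.2) + 30, 20, 2))
  rownames(coords) <- sprintf("bc%02d", 1:40)
  clones <- clones_from_lists(split(rownames(coords), rep(1:8, each = 5)))
  res <- baseline_centroid_cluster(clones, coords)
  region <- rep(1:2, each = 4)
  expect_equal(adjusted_rand_index(res$assignment$cluster, region), 1)
  expect_error(baseline_centroid_cluster(clones[1, ], coords), "at least 2")
  expect_error(baseline_centroid_cluster(clones, coords[1:10, ]), "missing")
})

test_that("ARI agrees with pair counting and the reference implementation", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c("b", "b", "a", "a")), 1)
  a <- c(1, 1, 1, 2, 2, 2); b <- c(1, 1, 2, 1, 2, 2)
  expect_equal(adjusted_rand_index(a, b), ari_pairs(a, b))
  skip_if_not_installed("mclust")
  set.seed(11)
  for (i in 1:10) {
    x <- sample(1:3, 12, replace = TRUE)
    y <- sample(1:4, 12, replace = TRUE)
    expect_equal(adjusted_rand_index(x, y), mclust::adjustedRandIndex(x, y),
                 tolerance = 1e-12)
  }
  expect_error(adjusted_rand_index(1:3, 1:4), "length")
})

test_that("the full clustering wrapper records outliers and distances", {
  set.seed(13)
  trajs <- random_trajectories(12, L = 6, D = 2, seed = 13)
  # make one trajectory wildly distant
  trajs[[12]]$grid <- trajs[[12]]$grid + 500
  res <- cluster_trajectories(trajs)
  expect_true("c12" %in% res$excluded_outliers)
  expect_false("c12" %in% res$assignment$clone_id)
  expect_equal(rownames(res$distance_matrix), res$assignment$clone_id)
  expect_true(all(res$silhouette_by_k$mean_silhouette >= -1 &
                    res$silhouette_by_k$mean_silhouette <= 1))
})
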