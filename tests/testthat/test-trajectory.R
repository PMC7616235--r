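lognorm_dataset <- function(m) {
  ds <- dataset_from_counts(m)
  ds$layers$lognorm <- Matrix::Matrix(m * 1.0, sparse = TRUE)
  dimnames(ds$layers$lognorm) <- dimnames(ds$counts)
  ds
}

test_that("PCA embedding recovers low-rank structure deterministically", {
  # rank-1 data: first component captures essentially all variance
  set.seed(1)
  u <- rnorm(30); v <- abs(rnorm(12))
  m <- round(outer(exp(u), v * 10))
  storage.mode(m) <- "integer"
  ds <- lognorm_dataset(m)
  emb <- embed_pca(ds, n_dims = 3)
  expect_gt(emb$var_explained[1] / sum(emb$var_explained), 0.999)
  # duplicate rows embed identically
  m2 <- rbind(m, m[1, , drop = FALSE])
  rownames(m2) <- sprintf("c%03d", seq_len(nrow(m2)))
  ds2 <- lognorm_dataset(m2)
  emb2 <- embed_pca(ds2, n_dims = 3)
  expect_equal(emb2$coords[1, ], emb2$coords[nrow(m2), ], ignore_attr = TRUE)
  expect_error(embed_pca(ds, n_dims = 100), "n_dims")
})

test_that("PCA matches an exact eigendecomposition on a two-cluster fixture", {
  set.seed(2)
  m <- rbind(matrix(rpois(10 * 6, 2), 10), matrix(rpois(10 * 6, 2) + 9L, 10))
  storage.mode(m) <- "integer"
  ds <- lognorm_dataset(m)
  emb <- embed_pca(ds, n_dims = 2)
  # exact dense covariance eigendecomposition oracle
  x <- sweep(m, 2, colMeans(m))
  eig <- eigen(crossprod(x) / (nrow(x) - 1))
  scores1 <- x %*% eig$vectors[, 1]
  expect_gt(abs(cor(scores1, emb$coords[, 1])), 1 - 1e-9)
  # component 1 separates the clusters
  expect_true(max(emb$coords[1:10, 1]) < min(emb$coords[11:20, 1]) ||
                min(emb$coords[1:10, 1]) > max(emb$coords[11:20, 1]))
})

line_coords <- function(n = 40) {
  x <- seq(0, 10, length.out = n)
  coords <- cbind(x, 0.5 * x)
  rownames(coords) <- sprintf("bc%03d", seq_len(n))
  coords
}

test_that("graph pseudotime is monotone along a line with root at zero", {
  coords <- line_coords()
  pt <- compute_pseudotime(coords, "bc001", k_neighbors = 3)
  expect_equal(pt$pseudotime[1], 0)
  expect_equal(cor(pt$pseudotime, seq_len(nrow(coords)), method = "spearman"), 1)
  expect_equal(range(pt$pseudotime), c(0, 1))
  expect_error(compute_pseudotime(coords, "nope", 3), "not found")
})

test_that("disconnected graphs error unless bridging is requested", {
  coords <- rbind(line_coords(10), line_coords(10) + 1000)
  rownames(coords) <- sprintf("bc%03d", 1:20)
  expect_error(compute_pseudotime(coords, "bc001", k_neighbors = 3),
               "disconnected")
  pt <- compute_pseudotime(coords, "bc001", k_neighbors = 3,
                           connect_components = TRUE)
  expect_equal(nrow(pt), 20)
  expect_true(all(is.finite(pt$pseudotime)))
  # far block comes after the near block
  expect_gt(min(pt$pseudotime[11:20]), max(pt$pseudotime[1:10]))
})

test_that("imported pseudotime is min-max scaled and validated", {
  out <- import_pseudotime(tibble::tibble(barcode = c("a", "b", "c"),
                                          value = c(2, 4, 6)))
  expect_equal(out$pseudotime, c(0, 0.5, 1))
  expect_error(import_pseudotime(tibble::tibble(barcode = c("a", "b"),
                                                value = c(3, 3))), "zero range")
  expect_error(import_pseudotime(tibble::tibble(barcode = "a", value = NaN)),
               "non-finite")
  expect_error(import_pseudotime(tibble::tibble(barcode = "a", value = 1),
                                 barcodes = c("a", "b")), "missing")
  # round trip with computed pseudotime is the identity
  pt <- compute_pseudotime(line_coords(), "bc001", 3)
  again <- import_pseudotime(pt)
  expect_equal(again$pseudotime, pt$pseudotime)
})

test_that("clone trajectories interpolate member cells onto the grid", {
  # exactly L cells at equally spaced pseudotimes: grid == cell coordinates
  L <- 20
  coords <- cbind(seq(0, 1, length.out = L), seq(2, 4, length.out = L))
  rownames(coords) <- sprintf("bc%03d", 1:L)
  pt <- tibble::tibble(barcode = rownames(coords),
                       pseudotime = seq(0, 1, length.out = L))
  tr <- build_clone_trajectory(rownames(coords), coords, pt, L = L, D_use = 2)
  expect_equal(tr$grid, unname(coords), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(tr$pseudotime_span, c(0, 1))
  # cells exactly on a line at uniform pseudotime reproduce the line
  n <- 57
  coords2 <- cbind(seq(0, 5, length.out = n), seq(1, -1, length.out = n))
  rownames(coords2) <- sprintf("bc%03d", 1:n)
  pt2 <- tibble::tibble(barcode = rownames(coords2),
                        pseudotime = seq(0, 1, length.out = n))
  tr2 <- build_clone_trajectory(rownames(coords2), coords2, pt2, L = 10,
                                D_use = 2, smooth = FALSE)
  want <- cbind(seq(0, 5, length.out = 10), seq(1, -1, length.out = 10))
  expect_lt(max(abs(tr2$grid - want)), 1e-9)
})

test_that("trajectory interpolation matches an independent oracle", {
  set.seed(6)
  n <- 15
  coords <- matrix(rnorm(n * 3), n, 3,
                   dimnames = list(sprintf("bc%03d", 1:n), NULL))
  ptv <- sort(runif(n))
  pt <- tibble::tibble(barcode = rownames(coords), pseudotime = ptv)
  L <- 8
  tr <- build_clone_trajectory(rownames(coords), coords, pt, L = L, D_use = 3,
                               smooth = FALSE)
  # oracle: explicit piecewise-linear interpolation over normalized times
  tn <- (ptv - min(ptv)) / (max(ptv) - min(ptv))
  grid_t <- seq(0, 1, length.out = L)
  oracle <- matrix(0, L, 3)
  for (g in seq_len(L)) {
    t0 <- grid_t[g]
    hi <- which(tn >= t0 - 1e-15)[1]
    if (hi == 1) { oracle[g, ] <- coords[1, ]; next }
    lo <- hi - 1
    w <- (t0 - tn[lo]) / (tn[hi] - tn[lo])
    oracle[g, ] <- (1 - w) * coords[lo, ] + w * coords[hi, ]
  }
  expect_lt(max(abs(tr$grid - oracle)), 1e-9)
})

test_that("trajectories are invariant to cell order and pseudotime rescaling", {
  set.seed(12)
  n <- 30
  coords <- matrix(rnorm(n * 4), n, 4,
                   dimnames = list(sprintf("bc%03d", 1:n), NULL))
  ptv <- runif(n)
  pt <- tibble::tibble(barcode = rownames(coords), pseudotime = ptv)
  bc <- rownames(coords)
  a <- build_clone_trajectory(bc, coords, pt, L = 10, D_use = 4)
  b <- build_clone_trajectory(sample(bc), coords, pt, L = 10, D_use = 4)
  expect_equal(a$grid, b$grid, tolerance = 1e-12)
  # affine rescaling of pseudotime changes nothing (clone-local normalization)
  pt_aff <- tibble::tibble(barcode = bc, pseudotime = 3 + 11 * ptv)
  c_ <- build_clone_trajectory(bc, coords, pt_aff, L = 10, D_use = 4)
  expect_equal(a$grid, c_$grid, tolerance = 1e-10)
  # degenerate clone: all members at one pseudotime
  flat <- tibble::tibble(barcode = bc, pseudotime = 0.4)
  expect_error(build_clone_trajectory(bc, coords, flat, L = 10), "identical")
})

test_that("subsampling a smooth clone perturbs the grid only modestly", {
  set.seed(3)
  n <- 120
  t_true <- sort(runif(n))
  coords <- cbind(t_true * 4 + rnorm(n, 0, 0.05),
                  sin(t_true * pi) + rnorm(n, 0, 0.05))
  rownames(coords) <- sprintf("bc%03d", 1:n)
  pt <- tibble::tibble(barcode = rownames(coords), pseudotime = t_true)
  full <- build_clone_trajectory(rownames(coords), coords, pt, L = 20, D_use = 2)
  sub <- build_clone_trajectory(sample(rownames(coords), 96), coords, pt,
                                L = 20, D_use = 2)
  expect_lt(max(abs(full$grid - sub$grid)), 0.5)
})
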