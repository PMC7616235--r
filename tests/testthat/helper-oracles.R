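# Independent oracles used to validate the package's implementations.

# Brute-force DTW: enumerate every monotone warping path on the La x Lb
# lattice (steps right, down, diagonal), sum local Euclidean costs, take the
# minimum. Exponential; only for small grids.
dtw_brute <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, ncol = 1)
  if (is.null(dim(b))) b <- matrix(b, ncol = 1)
  la <- nrow(a); lb <- nrow(b)
  local <- matrix(0, la, lb)
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    local[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  }
  best <- Inf
  walk <- function(i, j, cost) {
    cost <- cost + local[i, j]
    if (cost >= best) return(invisible())   # prune, preserves exact minimum
    if (i == la && j == lb) { best <<- cost; return(invisible()) }
    if (i < la) walk(i + 1, j, cost)
    if (j < lb) walk(i, j + 1, cost)
    if (i < la && j < lb) walk(i + 1, j + 1, cost)
  }
  walk(1, 1, 0)
  best
}

# Pair-counting ARI from first principles: loop over all item pairs.
ari_pairs <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (!sa && !sb) n00 <- n00 + 1
    else if (sa) n10 <- n10 + 1
    else n01 <- n01 + 1
  }
  2 * (n11 * n00 - n10 * n01) /
    ((n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00))
}

# Naive binned-control scoring: dense matrices, explicit loops, same
# documented sampling protocol (targets in order, bin pool in gene order,
# sample() under the seed) but independently coded arithmetic and binning.
score_gene_set_naive <- function(dataset, genes, n_bins, ctrl_per_gene, seed) {
  ln <- as.matrix(dataset$layers$lognorm)
  genes <- genes[genes %in% colnames(ln)]
  means <- colMeans(ln)
  ord <- order(means)                      # ties keep gene order (stable)
  n_genes <- ncol(ln)
  bin_of <- integer(n_genes)
  names(bin_of) <- colnames(ln)
  for (pos in seq_along(ord)) {
    bin_of[ord[pos]] <- floor((pos - 1) * n_bins / n_genes) + 1
  }
  ctrl <- withr::with_seed(as.integer(seed), {
    out <- list()
    for (g in genes) {
      pool <- colnames(ln)[bin_of == bin_of[[g]]]
      pool <- pool[pool != g]
      out[[g]] <- if (length(pool) <= ctrl_per_gene) pool
                  else sample(pool, ctrl_per_gene)
    }
    out
  })
  scores <- numeric(nrow(ln))
  ctrl_flat <- unlist(ctrl, use.names = FALSE)
  for (cell in seq_len(nrow(ln))) {
    tgt <- mean(ln[cell, genes])
    ctl <- mean(ln[cell, ctrl_flat])       # multiplicity preserved
    scores[cell] <- tgt - ctl
  }
  scores
}

# Exhaustive silhouette search over tree cuts using cluster::silhouette as
# the independent scorer.
best_k_exhaustive <- function(tree, d, k_min, k_max) {
  ks <- k_min:k_max
  sil <- vapply(ks, function(k) {
    lab <- stats::cutree(tree, k = k)
    mean(cluster::silhouette(lab, dmatrix = d)[, "sil_width"])
  }, numeric(1))
  ks[which.max(sil)]
}
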