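test_that("cells sharing both chain sequences form one clone, exact-match", {
  ds <- toy_dataset(n_cells = 4, n_clones = 2)
  clones <- assemble_clones(ds)
  expect_equal(nrow(clones), 2)
  expect_equal(clones$size, c(2L, 2L))
  expect_setequal(unlist(clones$barcodes), ds$barcodes)
  # one-nucleotide difference in alpha splits the clone
  ds2 <- toy_dataset(n_cells = 2, n_clones = 3)
  ds2$tcr$alpha_nt <- c("ACGTACGTAC", "ACGTACGTAT")  # differ at last base
  ds2$tcr$beta_nt <- "GGGGAAAACC"
  clones2 <- assemble_clones(ds2)
  expect_equal(nrow(clones2), 2)
  expect_equal(clones2$size, c(1L, 1L))
})

test_that("assembly is a partition with deterministic ids and recovers simulated clones", {
  cfg <- simulation_config(list(flat_pattern()), clones_per_pattern = 10,
                           cells_per_clone = c(10, 10), n_genes = 80,
                           n_marker_genes_per_program = 2)
  res <- simulate_dataset(cfg, seed = 3)
  ds <- res$dataset
  clones <- assemble_clones(ds)
  # exactly the generator's partition
  expect_equal(nrow(clones), 10)
  gt <- res$ground_truth$cells
  for (i in seq_len(nrow(clones))) {
    expect_setequal(clones$barcodes[[i]],
                    gt$barcode[gt$clone_id == clones$clone_id[i]])
  }
  # partition: every cell in exactly one clone
  all_bc <- unlist(clones$barcodes)
  expect_equal(sort(all_bc), sort(ds$barcodes))
  expect_false(anyDuplicated(all_bc) > 0)
  # ids stable across runs and cell order
  perm <- sample(seq_along(ds$barcodes))
  ds_perm <- subset_dataset(ds, cells = perm)
  clones_perm <- assemble_clones(ds_perm)
  expect_setequal(clones_perm$clone_id, clones$clone_id)
  # incomplete pair refuses assembly
  ds$tcr$complete[1] <- FALSE
  expect_error(assemble_clones(ds), "complete")
})

test_that("lineage calls use a strict 60% Cd8a-positive boundary", {
  clones <- clones_from_lists(list(sprintf("bc%02d", 1:10)))
  expect_equal(classify_lineage(clones, make_marker_dataset(7, 0))$lineage, "CD8")
  expect_equal(classify_lineage(clones, make_marker_dataset(6, 0))$lineage, "CD4")
  expect_equal(classify_lineage(clones, make_marker_dataset(0, 0))$lineage, "CD4")
  expect_error(classify_lineage(clones, dataset_from_counts(matrix(1L, 2, 1)),
                                gene = "Cd8a"), "not present")
})

test_that("Treg calls use a strict 10% Foxp3 boundary on CD4 clones only", {
  clones <- clones_from_lists(list(sprintf("bc%02d", 1:10)))
  cd4 <- classify_lineage(clones, make_marker_dataset(0, 2))
  expect_true(classify_treg(cd4, make_marker_dataset(0, 2))$is_treg)
  expect_false(classify_treg(cd4, make_marker_dataset(0, 1))$is_treg)
  cd8 <- classify_lineage(clones, make_marker_dataset(8, 2))
  expect_error(classify_treg(cd8, make_marker_dataset(8, 2)), "CD4")
  # wrapper handles mixed tables, CD8 clones get is_treg = FALSE
  both <- classify_clones(clones, make_marker_dataset(8, 9))
  expect_equal(both$lineage, "CD8")
  expect_false(both$is_treg)
})

test_that("classification is invariant to cell order within a clone", {
  ds <- make_marker_dataset(7, 2)
  a <- clones_from_lists(list(sprintf("bc%02d", 1:10)))
  b <- clones_from_lists(list(sprintf("bc%02d", c(5, 3, 9, 1, 10, 2, 8, 4, 7, 6))))
  expect_equal(classify_lineage(a, ds)$lineage, classify_lineage(b, ds)$lineage)
  expect_equal(classify_lineage(a, ds)$cd8a_fraction,
               classify_lineage(b, ds)$cd8a_fraction)
})

test_that("the expansion filter keeps clones > 15 cells with tumor presence", {
  ds <- two_tissue_dataset(100, 100)
  bc_t <- ds$barcodes[1:100]; bc_s <- ds$barcodes[101:200]
  clones <- clones_from_lists(list(
    bc_t[1:15],                       # size 15, in tumor -> removed
    bc_t[16:31],                      # size 16, in tumor -> kept
    bc_s[1:16],                       # size 16, spleen only -> removed
    c(bc_t[32:70], bc_s[17:52])       # size 75 -> kept
  ))
  clones <- clone_tissue_stats(clones, ds)
  kept <- filter_clones(clones, ds)
  expect_setequal(kept$clone_id, clones$clone_id[c(2, 4)])
  # additional floor for trajectory clustering
  kept75 <- filter_clones(clones, ds, size_ge = 75)
  expect_equal(kept75$clone_id, clones$clone_id[4])
  expect_error(filter_clones(dplyr::select(clones, -dplyr::starts_with("n_"),
                                           -dplyr::starts_with("freq_")),
                             ds, require_tissue = "lung"), "unknown tissue")
})

test_that("clone frequencies are fractions of all captured cells per tissue", {
  ds <- two_tissue_dataset(100, 50)
  bc_t <- ds$barcodes[1:100]; bc_s <- ds$barcodes[101:150]
  clones <- clones_from_lists(list(bc_t[1:5], bc_t[6:100], bc_s))
  expect_equal(clone_frequency(clones, ds, "tumor"), c(0.05, 0.95, 0))
  expect_equal(clone_frequency(clones, ds, "spleen"), c(0, 0, 1))
  # over any tissue the clone counts sum to the captured total
  st <- clone_tissue_stats(clones, ds)
  expect_equal(sum(st$n_tumor), 100)
  expect_equal(sum(st$n_spleen), 50)
  expect_equal(sum(st$freq_tumor), 1)
  expect_error(clone_frequency(clones, ds, "lung"), "no captured cells")
})

test_that("simulated tissue frequencies match the generator proportions", {
  cfg <- simulation_config(list(flat_pattern(tissue_split = c(0.6, 0))),
                           clones_per_pattern = 8,
                           cells_per_clone = c(100, 100), n_genes = 80,
                           n_marker_genes_per_program = 2)
  res <- simulate_dataset(cfg, seed = 8)
  ds <- res$dataset
  clones <- clone_tissue_stats(assemble_clones(ds), ds)
  # each clone contributes ~100 cells, ~60 tumor; binomial 95% CI around 0.6
  tumor_share <- clones$n_tumor / clones$size
  ci <- 1.96 * sqrt(0.6 * 0.4 / 100)
  expect_true(mean(abs(tumor_share - 0.6) < ci) >= 5 / 8)
  expect_lt(abs(mean(tumor_share) - 0.6), 3 * sqrt(0.6 * 0.4 / 800))
})

test_that("spatial distribution bias is spleen over tumor frequency", {
  ds <- two_tissue_dataset(100, 100)
  bc_t <- ds$barcodes[1:100]; bc_s <- ds$barcodes[101:200]
  clones <- clone_tissue_stats(clones_from_lists(list(
    c(bc_t[1:2], bc_s[1:2]),          # 0.02 / 0.02 -> 1
    bc_t[3:6],                        # tumor-confined -> 0
    c(bc_t[7:10], bc_s[3])            # 0.01 / 0.04 -> 0.25
  )), ds)
  out <- spatial_distribution_bias(clones)
  expect_equal(out$bias, c(1, 0, 0.25))
  spleen_only <- clone_tissue_stats(clones_from_lists(list(bc_s[10:12])), ds)
  expect_error(spatial_distribution_bias(spleen_only), "zero tumor")
})

test_that("repertoire overlap is the fraction of clones with a shared key", {
  a <- clones_from_lists(rep(list("x"), 4),
                         alpha = paste0("A", 1:4), beta = paste0("B", 1:4))
  expect_equal(repertoire_overlap(a, a, key = "pair_nt"), 1)
  expect_equal(repertoire_overlap(a, c("Z1", "Z2")), 0)
  expect_equal(repertoire_overlap(a, paste0("B", 1:3), key = "beta_nt"), 0.75)
  expect_error(repertoire_overlap(a[0, ], a), "empty")
})

test_that("top-n selection ranks by tumor frequency with stable ties", {
  clones <- tibble::tibble(clone_id = c("cc", "aa", "bb", "dd", "ee"),
                           freq_tumor = c(0.3, 0.1, 0.1, 0.5, 0.05))
  expect_equal(top_n_by_tumor_frequency(clones, 2)$clone_id, c("dd", "cc"))
  # tie at the boundary: alphabetical clone_id decides
  expect_equal(top_n_by_tumor_frequency(clones, 3)$clone_id,
               c("dd", "cc", "aa"))
  expect_equal(nrow(top_n_by_tumor_frequency(clones, 200)), 5)
})
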