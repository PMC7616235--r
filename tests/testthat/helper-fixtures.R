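# Shared fixtures, all built in code.

# A small deterministic dataset: 10 cells x 8 genes with lineage,
# mitochondrial and TR-V genes. Counts chosen by hand.
toy_genes <- c("Cd8a", "Foxp3", "mt-Co1", "Trav7-2", "Gzmb", "Tcf7",
               "Pdcd1", "Sell")

toy_counts <- function(n_cells = 10) {
  set.seed(99)
  m <- matrix(rpois(n_cells * length(toy_genes), 2), n_cells,
              dimnames = list(sprintf("bc%02d", seq_len(n_cells)), toy_genes))
  m
}

toy_tcr <- function(barcodes, n_clones = 2) {
  alpha <- c("ACGTACGTAC", "TTTTCCCCGG", "ACGTACGTAT")[seq_len(n_clones)]
  beta <- c("GGGGAAAACC", "CACACACACA", "GGGGAAAACT")[seq_len(n_clones)]
  idx <- rep_len(seq_len(n_clones), length(barcodes))
  tibble::tibble(barcode = barcodes, alpha_nt = alpha[idx],
                 beta_nt = beta[idx], alpha_cdr3_aa = "CAVF",
                 beta_cdr3_aa = "CASF", alpha_v = "TRAV1", alpha_j = "TRAJ1",
                 beta_v = "TRBV1", beta_j = "TRBJ1", complete = TRUE)
}

toy_dataset <- function(n_cells = 10, tissues = NULL, n_clones = 2) {
  m <- toy_counts(n_cells)
  bc <- rownames(m)
  if (is.null(tissues)) tissues <- rep_len(c("tumor", "spleen"), n_cells)
  meta <- tibble::tibble(barcode = bc, tissue = tissues, animal_id = "m1",
                         fatemap_label = "positive")
  tcell_dataset(m, colnames(m), bc, meta = meta, tcr = toy_tcr(bc, n_clones))
}

# A dataset built from an explicit counts matrix (rows become cells).
dataset_from_counts <- function(m, tissues = NULL, tcr = NULL) {
  if (is.null(rownames(m))) rownames(m) <- sprintf("c%03d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  meta <- NULL
  if (!is.null(tissues)) {
    meta <- tibble::tibble(barcode = rownames(m), tissue = tissues)
  }
  tcell_dataset(m, colnames(m), rownames(m), meta = meta, tcr = tcr)
}

# Clone tibble built directly from per-clone barcode lists.
clones_from_lists <- function(barcode_lists, alpha = NULL, beta = NULL) {
  n <- length(barcode_lists)
  if (is.null(alpha)) alpha <- sprintf("%s%04d", strrep("A", 6), seq_len(n))
  if (is.null(beta)) beta <- sprintf("%s%04d", strrep("G", 6), seq_len(n))
  tibble::tibble(clone_id = clone_id_hash(alpha, beta), alpha_nt = alpha,
                 beta_nt = beta,
                 size = lengths(barcode_lists),
                 barcodes = barcode_lists)
}

# Random trajectory set for distance/cluster tests.
random_trajectories <- function(n, L = 6, D = 2, seed = 1) {
  withr::with_seed(seed, {
    out <- lapply(seq_len(n), function(i) {
      structure(list(clone_id = sprintf("c%02d", i),
                     grid = matrix(rnorm(L * D), L, D),
                     n_cells = 10L, pseudotime_span = c(0, 1)),
                class = "clone_trajectory")
    })
    names(out) <- sprintf("c%02d", seq_len(n))
    class(out) <- "trajectory_set"
    out
  })
}

# Contig CSV fixture on disk; rows supplied as a tibble.
write_contig_csv <- function(rows, path = tempfile(fileext = ".csv")) {
  readr::write_csv(rows, path)
  path
}

contig_row <- function(barcode, chain, nt, umis = 5, productive = "true",
                       contig_id = paste0(barcode, "_", chain, "_", umis)) {
  tibble::tibble(barcode = barcode, contig_id = contig_id, chain = chain,
                 v_gene = "TRAV1", j_gene = "TRAJ1", cdr3 = "CAVRF",
                 cdr3_nt = substr(nt, 1, 9), productive = productive,
                 umis = umis, sequence = nt)
}

# Tiny simulation config (single flat pattern unless given) for fast tests.
flat_pattern <- function(P = 4, tissue_split = c(0.5, 0)) {
  anchors <- matrix(0, 2, P)
  pattern_spec("flat", anchors, c(0, 1),
               tibble::tibble(mean = 0.5, sd = 0.2, weight = 1),
               tissue_split = tissue_split)
}

# Cached full-scale benchmark run shared by the acceptance tests.
.acceptance_cache <- new.env(parent = emptyenv())

acceptance_benchmark <- function(seed = 42) {
  key <- paste0("run_", seed)
  if (!is.null(.acceptance_cache[[key]])) return(.acceptance_cache[[key]])
  outdir <- file.path(tempdir(), paste0("bench_", seed))
  cfg <- run_config(outdir, seed = seed, sim = default_five_pattern_config())
  run_pipeline(cfg)
  gt <- jsonlite::read_json(file.path(outdir, "ground_truth.json"),
                            simplifyVector = TRUE)
  report <- jsonlite::read_json(file.path(outdir, "report.json"),
                                simplifyVector = TRUE)
  clusters <- jsonlite::read_json(file.path(outdir, "clusters.json"))
  baseline <- jsonlite::read_json(file.path(outdir, "baseline_clusters.json"))
  pt <- readr::read_tsv(file.path(outdir, "pseudotime.tsv"),
                        show_col_types = FALSE, progress = FALSE)
  res <- list(outdir = outdir, cfg = cfg, gt = gt, report = report,
              clusters = clusters, baseline = baseline, pseudotime = pt)
  .acceptance_cache[[key]] <- res
  res
}

make_marker_dataset <- function(cd8a_positive, foxp3_positive, n = 10) {
  m <- matrix(0L, n, 3, dimnames = list(sprintf("bc%02d", 1:n),
                                        c("Cd8a", "Foxp3", "Gzmb")))
  m[seq_len(cd8a_positive), "Cd8a"] <- 2L
  m[seq_len(foxp3_positive), "Foxp3"] <- 1L
  m[, "Gzmb"] <- 1L
  dataset_from_counts(m, tissues = rep("tumor", n))
}

two_tissue_dataset <- function(n_tumor, n_spleen) {
  n <- n_tumor + n_spleen
  m <- matrix(1L, n, 2, dimnames = list(sprintf("bc%03d", 1:n),
                                        c("Cd8a", "Gzmb")))
  dataset_from_counts(m, tissues = rep(c("tumor", "spleen"),
                                       c(n_tumor, n_spleen)))
}

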