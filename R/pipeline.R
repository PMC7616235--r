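#' Pipeline run configuration
#'
#' Declarative description of one analysis run: either a simulation block or
#' paths to real inputs, the filtering/scoring/trajectory thresholds
#' (defaults follow the processing rules: 60% Cd8a / 10% Foxp3
#' classification, clone size > 15 with tumor presence, size >= 75 for
#' trajectory clustering, 200-5000 features, < 10% mitochondrial counts, 25
#' expression bins, 50 controls per gene, 20-point grids over 10 dimensions,
#' K in 2..10), a seed, and the output directory.
#'
#' @param outdir output directory for all artifacts.
#' @param seed integer seed for every stochastic step.
#' @param sim a [simulation_config()], or `NULL` when reading real inputs.
#' @param input list of paths (`matrix`, `genes`, `barcodes`, `contigs`,
#'   `contigs_dialect`, `meta`) used when `sim` is `NULL`.
#' @param qc list of [qc_filter()] arguments. Simulated data is far shallower
#'   than a real transcriptome, so when `sim` is given the feature floor
#'   defaults to 30 instead of 200.
#' @param clone list: `min_size`, `require_tissue`, `traj_min_size`.
#' @param score list: `n_bins`, `ctrl_per_gene`, `gmt` (gene-set file; the
#'   simulate step writes one with the ground-truth sets).
#' @param traj list: `n_dims`, `L`, `D_use`, `k_neighbors`, `pseudotime_dims`
#'   (leading components the pseudotime graph is built on), `root_gene_set`,
#'   `pseudotime_file` (external pseudotime takes precedence when given).
#' @param clusterp list: `k_min`, `k_max`, `metric`, `linkage`,
#'   `outlier_rule`, `manual_outliers`.
#' @param overwrite allow steps to replace existing outputs.
#' @return A `run_config` list.
#' @export
run_config <- function(outdir, seed = 1, sim = NULL, input = NULL,
                       qc = list(), clone = list(), score = list(),
                       traj = list(), clusterp = list(), overwrite = FALSE) {
  qc_def <- list(min_features = if (is.null(sim)) 200 else 30,
                 max_features = 5000, max_mito_fraction = 0.10,
                 require_complete_tcr = TRUE, mito_prefix = "mt-")
  cfg <- list(
    outdir = outdir, seed = as.integer(seed), sim = sim, input = input,
    qc = utils::modifyList(qc_def, qc),
    clone = utils::modifyList(list(min_size = 16, require_tissue = "tumor",
                                   traj_min_size = 75), clone),
    # simulated panels are ~300 genes: bins must stay wider than the gene
    # modules, so the bin count drops with the panel (25 suits transcriptomes)
    score = utils::modifyList(list(n_bins = if (is.null(sim)) 25 else 6,
                                   ctrl_per_gene = 50, gmt = NULL), score),
    traj = utils::modifyList(list(n_dims = 50, L = 20, D_use = 10,
                                  k_neighbors = 15, pseudotime_dims = 10,
                                  root_gene_set = "naive_program",
                                  pseudotime_file = NULL), traj),
    clusterp = utils::modifyList(list(k_min = 2, k_max = 10, metric = "dtw",
                                      linkage = "average",
                                      outlier_rule = "iqr",
                                      manual_outliers = character()), clusterp),
    overwrite = overwrite
  )
  class(cfg) <- "run_config"
  cfg
}

out_path <- function(cfg, ...) file.path(cfg$outdir, ...)

check_fresh <- function(cfg, path) {
  if (file.exists(path) && !cfg$overwrite) {
    stop("output ", path, " already exists (write-once; set overwrite = TRUE)",
         call. = FALSE)
  }
}

require_upstream <- function(cfg, path, producer) {
  if (!file.exists(path)) {
    stop("missing upstream artifact ", path, "; run ", producer, " first",
         call. = FALSE)
  }
  path
}

#' Pipeline step: simulate a dataset and write it in on-disk formats
#'
#' Writes `counts/` (mtx + sidecars), `contigs.csv` (contig-CSV dialect with
#' a full-length `sequence` column), `metadata.tsv`, `gene_sets.gmt`
#' (ground-truth program and module sets) and `ground_truth.json`.
#'
#' @param cfg a [run_config()] with a `sim` block.
#' @return The simulation result, invisibly.
#' @export
pipeline_simulate <- function(cfg) {
  if (is.null(cfg$sim)) stop("config has no simulation block", call. = FALSE)
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  check_fresh(cfg, out_path(cfg, "ground_truth.json"))
  res <- simulate_dataset(cfg$sim, cfg$seed)
  ds <- res$dataset
  write_counts(ds, out_path(cfg, "counts"))
  # one productive contig per chain per cell, in the contig-CSV dialect
  contigs <- dplyr::bind_rows(
    dplyr::transmute(ds$tcr, barcode = .data$barcode,
                     contig_id = paste0(.data$barcode, "_1"), chain = "TRA",
                     v_gene = .data$alpha_v, j_gene = .data$alpha_j,
                     cdr3 = .data$alpha_cdr3_aa, cdr3_nt = .data$alpha_nt,
                     sequence = .data$alpha_nt, productive = "true", umis = 4),
    dplyr::transmute(ds$tcr, barcode = .data$barcode,
                     contig_id = paste0(.data$barcode, "_2"), chain = "TRB",
                     v_gene = .data$beta_v, j_gene = .data$beta_j,
                     cdr3 = .data$beta_cdr3_aa, cdr3_nt = .data$beta_nt,
                     sequence = .data$beta_nt, productive = "true", umis = 4)
  ) |> dplyr::arrange(.data$barcode, .data$contig_id)
  readr::write_csv(contigs, out_path(cfg, "contigs.csv"))
  readr::write_tsv(ds$meta, out_path(cfg, "metadata.tsv"))
  write_gmt(res$ground_truth$gene_sets, out_path(cfg, "gene_sets.gmt"))
  jsonlite::write_json(
    list(cells = res$ground_truth$cells, clones = res$ground_truth$clones,
         params = res$ground_truth$params),
    out_path(cfg, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

#' Load the run's dataset from disk and apply QC + TR-V filters
#'
#' Shared by the clones/score/trajectories steps so they all see an identical
#' filtered dataset.
#'
#' @param cfg a [run_config()].
#' @return A filtered, log-normalized [tcell_dataset()].
#' @export
load_filtered_dataset <- function(cfg) {
  if (!is.null(cfg$sim) || file.exists(out_path(cfg, "counts", "matrix.mtx"))) {
    mtx <- require_upstream(cfg, out_path(cfg, "counts", "matrix.mtx"),
                            "pipeline_simulate")
    ds <- read_counts(mtx, out_path(cfg, "counts", "genes.tsv"),
                      out_path(cfg, "counts", "barcodes.tsv"))
    tcr <- read_tcr_table(require_upstream(cfg, out_path(cfg, "contigs.csv"),
                                           "pipeline_simulate"), "contig_csv")
    meta <- readr::read_tsv(out_path(cfg, "metadata.tsv"),
                            show_col_types = FALSE, progress = FALSE)
  } else {
    inp <- cfg$input
    if (is.null(inp)) stop("config has neither simulation outputs nor inputs",
                           call. = FALSE)
    ds <- read_counts(inp$matrix, inp$genes, inp$barcodes)
    tcr <- read_tcr_table(inp$contigs, inp$contigs_dialect %||% "contig_csv")
    meta <- readr::read_tsv(inp$meta, show_col_types = FALSE, progress = FALSE)
  }
  ds <- tcell_dataset(ds$counts, ds$gene_ids, ds$barcodes, meta = meta, tcr = tcr)
  ds <- do.call(qc_filter, c(list(ds), cfg$qc))
  rep <- qc_report(ds)
  ds <- drop_tcr_variable_genes(ds)
  ds <- lognormalize(ds)
  attr(ds, "qc_report") <- rep
  ds
}

#' Pipeline step: assemble, classify and filter clones
#'
#' Writes `clones.tsv` (one row per retained clone with lineage, Treg flag,
#' per-tissue counts/frequencies and spatial distribution bias),
#' `clone_members.tsv` (clone_id, barcode) and `qc_report.json`.
#'
#' @param cfg a [run_config()].
#' @return The clone tibble, invisibly.
#' @export
pipeline_clones <- function(cfg) {
  check_fresh(cfg, out_path(cfg, "clones.tsv"))
  ds <- load_filtered_dataset(cfg)
  clones <- assemble_clones(ds) |>
    classify_clones(ds) |>
    clone_tissue_stats(ds) |>
    filter_clones(ds, min_size = cfg$clone$min_size,
                  require_tissue = cfg$clone$require_tissue) |>
    spatial_distribution_bias()
  jsonlite::write_json(qc_report(ds), out_path(cfg, "qc_report.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_tsv(
    tidyr::unnest(dplyr::select(clones, "clone_id", "barcodes"),
                  "barcodes") |> dplyr::rename(barcode = "barcodes"),
    out_path(cfg, "clone_members.tsv"))
  readr::write_tsv(dplyr::select(clones, -"barcodes"), out_path(cfg, "clones.tsv"))
  invisible(clones)
}

read_clones_artifact <- function(cfg) {
  tab <- readr::read_tsv(
    require_upstream(cfg, out_path(cfg, "clones.tsv"), "pipeline_clones"),
    show_col_types = FALSE, progress = FALSE)
  members <- readr::read_tsv(out_path(cfg, "clone_members.tsv"),
                             show_col_types = FALSE, progress = FALSE)
  tab$barcodes <- unname(split(members$barcode, members$clone_id)[tab$clone_id])
  tibble::as_tibble(tab)
}

#' Pipeline step: gene-set scores and cell-cycle phases
#'
#' Scores every set of the run's GMT file; if a set named `cycling` (or the
#' pair `cycling_s`/`cycling_g2m`) is present its halves are used as S/G2M
#' sets for phase assignment. Writes `scores.tsv` (long: barcode, score_name,
#' value) and, when phases were assigned, `phases.tsv`.
#'
#' @param cfg a [run_config()].
#' @return Long score tibble, invisibly.
#' @export
pipeline_score <- function(cfg) {
  check_fresh(cfg, out_path(cfg, "scores.tsv"))
  ds <- load_filtered_dataset(cfg)
  gmt_path <- cfg$score$gmt %||% out_path(cfg, "gene_sets.gmt")
  sets <- read_gmt(require_upstream(cfg, gmt_path, "pipeline_simulate"))
  long <- purrr::imap_dfr(sets, function(genes, nm) {
    sc <- score_gene_set(ds, genes, nm, n_bins = cfg$score$n_bins,
                         ctrl_per_gene = cfg$score$ctrl_per_gene,
                         seed = cfg$seed)
    tibble::tibble(barcode = sc$barcode, score_name = nm, value = sc$score)
  })
  readr::write_tsv(long, out_path(cfg, "scores.tsv"))
  s_genes <- g2m_genes <- NULL
  if (all(c("cycling_s", "cycling_g2m") %in% names(sets))) {
    s_genes <- sets$cycling_s; g2m_genes <- sets$cycling_g2m
  } else if ("cycling" %in% names(sets)) {
    g <- sets$cycling
    s_genes <- g[seq_len(floor(length(g) / 2))]
    g2m_genes <- setdiff(g, s_genes)
  }
  if (!is.null(s_genes)) {
    phases <- assign_cycle_phase(ds, s_genes, g2m_genes, seed = cfg$seed,
                                 n_bins = cfg$score$n_bins,
                                 ctrl_per_gene = cfg$score$ctrl_per_gene)
    readr::write_tsv(phases, out_path(cfg, "phases.tsv"))
  }
  invisible(long)
}

#' Pipeline step: embedding, pseudotime and per-clone trajectories
#'
#' PCA embedding of the filtered log-normalized data, graph pseudotime from a
#' root cell picked by the naive/progenitor gene set (or an imported external
#' pseudotime when `traj$pseudotime_file` is set, which takes precedence),
#' and resampled trajectories for all clones at or above the trajectory size
#' floor. Writes `embedding.tsv`, `pseudotime.tsv`, `trajectories.tsv`.
#'
#' @param cfg a [run_config()].
#' @return The `trajectory_set`, invisibly.
#' @export
pipeline_trajectories <- function(cfg) {
  check_fresh(cfg, out_path(cfg, "trajectories.tsv"))
  ds <- load_filtered_dataset(cfg)
  clones <- read_clones_artifact(cfg)
  emb <- embed_pca(ds, n_dims = min(cfg$traj$n_dims,
                                    min(dim(ds$counts)) - 1L))
  if (!is.null(cfg$traj$pseudotime_file)) {
    pt_tab <- readr::read_tsv(cfg$traj$pseudotime_file, show_col_types = FALSE,
                              progress = FALSE)
    pt <- import_pseudotime(pt_tab, barcodes = ds$barcodes)
  } else {
    sets <- read_gmt(require_upstream(cfg, cfg$score$gmt %||%
                                        out_path(cfg, "gene_sets.gmt"),
                                      "pipeline_simulate"))
    root <- select_root_cell(ds, sets[[cfg$traj$root_gene_set]])
    pdims <- min(cfg$traj$pseudotime_dims, ncol(emb$coords))
    pt <- compute_pseudotime(emb$coords[, seq_len(pdims), drop = FALSE], root,
                             k_neighbors = cfg$traj$k_neighbors,
                             connect_components = TRUE)
  }
  big <- filter_clones(clones, ds, min_size = cfg$clone$min_size,
                       require_tissue = cfg$clone$require_tissue,
                       size_ge = cfg$clone$traj_min_size)
  if (nrow(big) < 2) stop("fewer than 2 clones reach the trajectory size floor",
                          call. = FALSE)
  trajs <- build_clone_trajectories(big, emb, pt, L = cfg$traj$L,
                                    D_use = cfg$traj$D_use)
  emb_tab <- tibble::as_tibble(emb$coords, .name_repair = "minimal")
  names(emb_tab) <- sprintf("PC%d", seq_len(ncol(emb$coords)))
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(barcode = ds$barcodes),
                                    emb_tab),
                   out_path(cfg, "embedding.tsv"))
  readr::write_tsv(pt, out_path(cfg, "pseudotime.tsv"))
  readr::write_tsv(tidy.trajectory_set(trajs), out_path(cfg, "trajectories.tsv"))
  invisible(trajs)
}

read_trajectories_artifact <- function(cfg) {
  tab <- readr::read_tsv(
    require_upstream(cfg, out_path(cfg, "trajectories.tsv"),
                     "pipeline_trajectories"),
    show_col_types = FALSE, progress = FALSE)
  ids <- unique(tab$clone_id)
  out <- lapply(ids, function(id) {
    sub <- tab[tab$clone_id == id, ]
    L <- max(sub$point); D <- max(sub$dim)
    grid <- matrix(0, L, D)
    grid[cbind(sub$point, sub$dim)] <- sub$value
    structure(list(clone_id = id, grid = grid, n_cells = NA_integer_,
                   pseudotime_span = c(NA_real_, NA_real_)),
              class = "clone_trajectory")
  })
  names(out) <- ids
  class(out) <- "trajectory_set"
  out
}

#' Pipeline step: trajectory clustering and the centroid baseline
#'
#' Runs trajectory-similarity clustering on the stored trajectories and the
#' first-moment centroid baseline on the stored 2-D embedding slice. Writes
#' `distance.tsv`, `clusters.json` and `baseline_clusters.json`.
#'
#' @param cfg a [run_config()].
#' @return The `traj_clusters` result, invisibly.
#' @export
pipeline_cluster <- function(cfg) {
  check_fresh(cfg, out_path(cfg, "clusters.json"))
  trajs <- read_trajectories_artifact(cfg)
  cp <- cfg$clusterp
  res <- cluster_trajectories(trajs, metric = cp$metric,
                              outlier_rule = cp$outlier_rule,
                              manual_outliers = cp$manual_outliers,
                              linkage = cp$linkage,
                              k_min = cp$k_min, k_max = cp$k_max)
  d <- res$distance_matrix
  readr::write_tsv(dplyr::bind_cols(tibble::tibble(clone_id = rownames(d)),
                                    tibble::as_tibble(as.data.frame(d))),
                   out_path(cfg, "distance.tsv"))
  jsonlite::write_json(cluster_result_json(res), out_path(cfg, "clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  emb_tab <- readr::read_tsv(
    require_upstream(cfg, out_path(cfg, "embedding.tsv"),
                     "pipeline_trajectories"),
    show_col_types = FALSE, progress = FALSE)
  coords <- as.matrix(emb_tab[, -1])
  rownames(coords) <- emb_tab$barcode
  clones <- read_clones_artifact(cfg)
  big <- clones[clones$clone_id %in% names(trajs), ]
  base <- baseline_centroid_cluster(big, coords, k_min = cp$k_min,
                                    k_max = cp$k_max, linkage = cp$linkage)
  jsonlite::write_json(cluster_result_json(base),
                       out_path(cfg, "baseline_clusters.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}

cluster_result_json <- function(res) {
  list(K = res$K,
       assignment = stats::setNames(as.list(res$assignment$cluster),
                                    res$assignment$clone_id),
       silhouette_by_k = res$silhouette_by_k,
       excluded_outliers = res$excluded_outliers,
       linkage = list(merge = res$tree$merge, height = res$tree$height,
                      labels = res$tree$labels))
}

#' Pipeline step: aggregate run report
#'
#' Collects clone statistics (sizes, lineage composition, spatial
#' distribution bias, cycling fractions and mean scores where computed),
#' cluster composition with per-cluster tissue distribution, and — when the
#' run was simulated — adjusted Rand indices of the trajectory clustering and
#' the centroid baseline against the ground-truth patterns. All parameters
#' are echoed. Writes `report.json`.
#'
#' @param cfg a [run_config()].
#' @return The report list, invisibly.
#' @export
pipeline_report <- function(cfg) {
  check_fresh(cfg, out_path(cfg, "report.json"))
  clones <- read_clones_artifact(cfg)
  clusters <- jsonlite::read_json(
    require_upstream(cfg, out_path(cfg, "clusters.json"), "pipeline_cluster"))
  baseline <- jsonlite::read_json(out_path(cfg, "baseline_clusters.json"))
  assign_tab <- tibble::tibble(
    clone_id = names(clusters$assignment),
    cluster = unlist(clusters$assignment, use.names = FALSE))
  tab <- dplyr::left_join(assign_tab, dplyr::select(clones, -"barcodes"),
                          by = "clone_id")
  freq_cols <- grep("^freq_", names(tab), value = TRUE)
  comp <- tab |>
    dplyr::group_by(.data$cluster) |>
    dplyr::summarise(n_clones = dplyr::n(),
                     mean_size = mean(.data$size),
                     mean_bias = mean(.data$bias),
                     dplyr::across(dplyr::all_of(freq_cols), mean),
                     .groups = "drop")
  report <- list(
    n_clones = nrow(clones),
    lineage_composition = as.list(table(clones$lineage)),
    n_treg = sum(clones$is_treg),
    K = clusters$K,
    cluster_composition = comp,
    baseline_K = baseline$K,
    excluded_outliers = clusters$excluded_outliers
  )
  phases_path <- out_path(cfg, "phases.tsv")
  if (file.exists(phases_path)) {
    phases <- readr::read_tsv(phases_path, show_col_types = FALSE,
                              progress = FALSE)
    report$cycling_fraction_overall <- mean(phases$phase == "G2M/S")
  }
  gt_path <- out_path(cfg, "ground_truth.json")
  if (file.exists(gt_path)) {
    gt <- jsonlite::read_json(gt_path, simplifyVector = TRUE)
    truth <- gt$clones$pattern[match(assign_tab$clone_id, gt$clones$clone_id)]
    report$ari_trajectory <- adjusted_rand_index(assign_tab$cluster, truth)
    base_tab <- tibble::tibble(
      clone_id = names(baseline$assignment),
      cluster = unlist(baseline$assignment, use.names = FALSE))
    truth_b <- gt$clones$pattern[match(base_tab$clone_id, gt$clones$clone_id)]
    report$ari_baseline <- adjusted_rand_index(base_tab$cluster, truth_b)
  }
  report$params <- cfg[c("seed", "qc", "clone", "score", "traj", "clusterp")]
  jsonlite::write_json(report, out_path(cfg, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' Run the whole pipeline
#'
#' Executes the requested steps in order and writes the resolved
#' configuration alongside the artifacts for reproducibility.
#'
#' @param cfg a [run_config()].
#' @param steps subset of steps to run, in pipeline order.
#' @return The report list (invisibly) when the report step runs.
#' @export
run_pipeline <- function(cfg, steps = c("simulate", "clones", "score",
                                        "trajectories", "cluster", "report")) {
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  cfg_json <- cfg
  cfg_json$sim <- if (is.null(cfg$sim)) NULL else "<simulation_config>"
  jsonlite::write_json(unclass(cfg_json), out_path(cfg, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  out <- NULL
  for (s in steps) {
    out <- switch(s,
                  simulate = pipeline_simulate(cfg),
                  clones = pipeline_clones(cfg),
                  score = pipeline_score(cfg),
                  trajectories = pipeline_trajectories(cfg),
                  cluster = pipeline_cluster(cfg),
                  report = pipeline_report(cfg),
                  stop("unknown step '", s, "'", call. = FALSE))
  }
  invisible(out)
}
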