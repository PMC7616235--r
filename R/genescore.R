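#' Library-size log-normalization
#'
#' Scales each cell's counts to a common total (`scale`, default 1e4) and
#' applies `log(1 + x)`. The result is stored as the `"lognorm"` layer and is
#' the expression channel used by scoring, PCA and trajectories.
#'
#' @param dataset a [tcell_dataset()] with raw counts.
#' @param scale target per-cell total.
#' @return The dataset with a `"lognorm"` layer added.
#' @export
lognormalize <- function(dataset, scale = 1e4) {
  stopifnot(inherits(dataset, "tcell_dataset"))
  totals <- Matrix::rowSums(dataset$counts)
  if (any(totals == 0)) {
    stop(sum(totals == 0), " cell(s) with zero total counts", call. = FALSE)
  }
  norm <- Matrix::Diagonal(x = scale / totals) %*% dataset$counts
  norm@x <- log1p(norm@x)
  dimnames(norm) <- dimnames(dataset$counts)
  dataset$layers$lognorm <- methods::as(norm, "CsparseMatrix")
  dataset
}

get_layer <- function(dataset, layer = "lognorm") {
  m <- dataset$layers[[layer]]
  if (is.null(m)) stop("layer '", layer, "' not found; run lognormalize()",
                       call. = FALSE)
  m
}

#' Bin genes by mean expression
#'
#' Genes are ranked by their mean log-normalized expression over all cells and
#' cut into `n_bins` (nearly) equal-size bins. Deterministic: ties in the mean
#' are broken by gene order.
#'
#' @param dataset dataset with a lognorm layer.
#' @param n_bins number of expression bins.
#' @return Integer vector of bin labels named by gene id.
#' @export
expression_bins <- function(dataset, n_bins = 25) {
  ln <- get_layer(dataset)
  n_genes <- ncol(ln)
  if (n_bins > n_genes) stop("n_bins exceeds the number of genes", call. = FALSE)
  means <- Matrix::colMeans(ln)
  r <- rank(means, ties.method = "first")
  bins <- as.integer(floor((r - 1) * n_bins / n_genes) + 1L)
  stats::setNames(bins, colnames(ln))
}

#' Gene-set score with expression-matched binned controls
#'
#' For every target gene, `ctrl_per_gene` control genes are sampled without
#' replacement from the target's expression bin (target excluded; if the bin
#' is smaller than `ctrl_per_gene` the whole bin is used). The per-cell score
#' is the mean log-normalized expression of the target genes minus the mean
#' over the pooled control draws (with multiplicity). Genes of the set absent
#' from the dataset are dropped with a warning; an empty intersection is an
#' error.
#'
#' Sampling protocol (fixed so results are reproducible given `seed`): target
#' genes are processed in the order supplied, each bin pool is in gene-column
#' order, and draws use `sample()` under `withr::with_seed(seed)`.
#'
#' @param dataset dataset with a lognorm layer.
#' @param genes character vector of target gene symbols.
#' @param name score name.
#' @param n_bins number of expression bins.
#' @param ctrl_per_gene control genes sampled per target gene.
#' @param seed integer seed for control sampling.
#' @return A tibble (`barcode`, `score`) with attributes `score_name`,
#'   `control_pool` (named list: target gene -> sampled controls) and `seed`.
#' @export
score_gene_set <- function(dataset, genes, name = "score", n_bins = 25,
                           ctrl_per_gene = 50, seed = 0) {
  ln <- get_layer(dataset)
  present <- intersect(genes, colnames(ln))
  if (length(present) < length(genes)) {
    warning(length(genes) - length(present), " gene(s) of set '", name,
            "' absent from the dataset and dropped", call. = FALSE)
  }
  if (length(present) == 0) {
    stop("no gene of set '", name, "' present in the dataset", call. = FALSE)
  }
  bins <- expression_bins(dataset, n_bins)
  all_genes <- colnames(ln)
  control_pool <- withr::with_seed(as.integer(seed), {
    lapply(stats::setNames(present, present), function(g) {
      pool <- all_genes[bins == bins[[g]]]
      pool <- pool[pool != g]
      if (length(pool) <= ctrl_per_gene) pool
      else sample(pool, ctrl_per_gene)
    })
  })
  ctrl_all <- unlist(control_pool, use.names = FALSE)
  target_mean <- Matrix::rowSums(ln[, present, drop = FALSE]) / length(present)
  ctrl_mat <- ln[, ctrl_all, drop = FALSE]          # duplicated columns kept
  ctrl_mean <- Matrix::rowSums(ctrl_mat) / length(ctrl_all)
  out <- tibble::tibble(barcode = rownames(ln),
                        score = as.numeric(target_mean - ctrl_mean))
  attr(out, "score_name") <- name
  attr(out, "control_pool") <- control_pool
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Assign cell-cycle phase from S and G2M gene-set scores
#'
#' Scores both sets with [score_gene_set()]; a cell is proliferating
#' (`"G2M/S"`) when the larger of its two scores is strictly positive and
#' quiescent (`"G1"`) otherwise — the two-way collapse of the usual
#' three-phase call. `three_way = TRUE` instead splits proliferating cells
#' into `"S"` / `"G2M"` by the larger score.
#'
#' @param dataset dataset with a lognorm layer.
#' @param s_genes,g2m_genes gene symbol vectors for the S and G2M programs.
#' @param seed seed for control sampling (shared by both scores).
#' @param three_way return S/G2M/G1 instead of the two-way collapse.
#' @inheritParams score_gene_set
#' @return A tibble: `barcode`, `s_score`, `g2m_score`, `phase`.
#' @export
assign_cycle_phase <- function(dataset, s_genes, g2m_genes, seed = 0,
                               n_bins = 25, ctrl_per_gene = 50,
                               three_way = FALSE) {
  s <- score_gene_set(dataset, s_genes, "S", n_bins, ctrl_per_gene, seed)
  g2m <- score_gene_set(dataset, g2m_genes, "G2M", n_bins, ctrl_per_gene, seed)
  out <- tibble::tibble(barcode = s$barcode, s_score = s$score,
                        g2m_score = g2m$score)
  top <- pmax(out$s_score, out$g2m_score)
  out$phase <- if (three_way) {
    dplyr::case_when(top <= 0 ~ "G1",
                     out$s_score >= out$g2m_score ~ "S",
                     TRUE ~ "G2M")
  } else ifelse(top > 0, "G2M/S", "G1")
  out
}

#' Fraction of a clone's cells in G2M/S phase within a tissue
#'
#' @param clones clone tibble.
#' @param phases tibble from [assign_cycle_phase()].
#' @param dataset the [tcell_dataset()] (for tissue labels).
#' @param tissue tissue to restrict to; `NULL` uses all member cells. A clone
#'   with no cells in the restriction is an error.
#' @return `clones` with an added `cycling_fraction` column.
#' @export
cycling_fraction <- function(clones, phases, dataset, tissue = NULL) {
  cyc <- stats::setNames(phases$phase %in% c("G2M/S", "S", "G2M"),
                         phases$barcode)
  tiss <- if (is.null(tissue)) NULL else
    stats::setNames(dataset_tissues(dataset), dataset$barcodes)
  frac <- vapply(seq_len(nrow(clones)), function(i) {
    bc <- clones$barcodes[[i]]
    if (!is.null(tissue)) bc <- bc[tiss[bc] == tissue]
    if (length(bc) == 0) {
      stop("clone ", clones$clone_id[i], " has no cells in tissue '", tissue,
           "'", call. = FALSE)
    }
    mean(cyc[bc])
  }, numeric(1))
  clones$cycling_fraction <- frac
  clones
}

#' Clone-level mean of a per-cell score
#'
#' Arithmetic mean of a score over a clone's member cells, optionally
#' restricted to one tissue. An empty restriction is an error; use
#' [has_min_cells_per_tissue()] to pre-filter clones.
#'
#' @param clones clone tibble.
#' @param scores tibble with `barcode` and `score` columns (from
#'   [score_gene_set()]).
#' @param dataset dataset, required when `tissue` is given.
#' @param tissue optional tissue restriction.
#' @param col name of the output column (defaults to the score's name with an
#'   optional `_<tissue>` suffix).
#' @return `clones` with the mean-score column added.
#' @export
clone_mean_score <- function(clones, scores, dataset = NULL, tissue = NULL,
                             col = NULL) {
  val <- stats::setNames(scores$score, scores$barcode)
  tiss <- NULL
  if (!is.null(tissue)) {
    if (is.null(dataset)) stop("dataset required for tissue restriction", call. = FALSE)
    tiss <- stats::setNames(dataset_tissues(dataset), dataset$barcodes)
  }
  m <- vapply(seq_len(nrow(clones)), function(i) {
    bc <- clones$barcodes[[i]]
    if (!is.null(tissue)) bc <- bc[tiss[bc] == tissue]
    if (length(bc) == 0) {
      stop("clone ", clones$clone_id[i], " has no cells in the restriction",
           call. = FALSE)
    }
    mean(val[bc])
  }, numeric(1))
  if (is.null(col)) {
    nm <- attr(scores, "score_name")
    if (is.null(nm)) nm <- "score"
    col <- if (is.null(tissue)) paste0("mean_", nm)
           else paste0("mean_", nm, "_", tissue)
  }
  clones[[col]] <- m
  clones
}
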