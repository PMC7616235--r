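#' Assemble clonal populations from TCR identity
#'
#' Cells sharing identical full alpha AND beta V(D)J nucleotide sequences form
#' one clonal population. Every cell must carry a complete chain pair (run
#' [qc_filter()] with `require_complete_tcr = TRUE` first). Clone ids are the
#' first 12 hex characters of the SHA-1 of `"alpha_nt|beta_nt"`, so they are
#' stable across runs and machines.
#'
#' @param dataset a [tcell_dataset()] with a TCR table.
#' @return A tibble with one row per clone: `clone_id`, `alpha_nt`, `beta_nt`,
#'   `size`, and a `barcodes` list-column of member cells, sorted by
#'   decreasing size then clone_id.
#' @export
assemble_clones <- function(dataset) {
  stopifnot(inherits(dataset, "tcell_dataset"))
  if (is.null(dataset$tcr)) stop("dataset has no TCR table", call. = FALSE)
  tcr <- dataset$tcr[match(dataset$barcodes, dataset$tcr$barcode), ]
  if (anyNA(tcr$complete) || !all(tcr$complete)) {
    stop("all cells must have a complete TCR chain pair; run qc_filter() ",
         "with require_complete_tcr = TRUE", call. = FALSE)
  }
  tcr |>
    dplyr::group_by(.data$alpha_nt, .data$beta_nt) |>
    dplyr::summarise(size = dplyr::n(),
                     barcodes = list(.data$barcode), .groups = "drop") |>
    dplyr::mutate(clone_id = clone_id_hash(.data$alpha_nt, .data$beta_nt)) |>
    dplyr::select("clone_id", "alpha_nt", "beta_nt", "size", "barcodes") |>
    dplyr::arrange(dplyr::desc(.data$size), .data$clone_id)
}

#' Deterministic clone identifier
#' @param alpha_nt,beta_nt chain nucleotide sequences.
#' @return 12-hex-character SHA-1 prefix of `"alpha|beta"`.
#' @export
clone_id_hash <- function(alpha_nt, beta_nt) {
  vapply(paste(alpha_nt, beta_nt, sep = "|"), function(s) {
    substr(digest::digest(s, algo = "sha1", serialize = FALSE), 1, 12)
  }, character(1), USE.NAMES = FALSE)
}

frac_expressing <- function(clones, dataset, gene) {
  if (!gene %in% dataset$gene_ids) {
    stop("gene '", gene, "' not present in the dataset", call. = FALSE)
  }
  pos <- dataset$counts[, gene] > 0
  vapply(clones$barcodes, function(bc) mean(pos[bc]), numeric(1))
}

#' Classify clone lineage from Cd8a expression
#'
#' A clone is CD8 when strictly more than `threshold` (default 60%) of its
#' member cells express the lineage gene (raw count > 0), CD4 otherwise.
#'
#' @param clones clone tibble from [assemble_clones()].
#' @param dataset the [tcell_dataset()] (raw counts used).
#' @param gene lineage marker gene symbol.
#' @param threshold strict fraction above which the clone is called CD8.
#' @return `clones` with added `cd8a_fraction` and `lineage` columns.
#' @export
classify_lineage <- function(clones, dataset, gene = "Cd8a", threshold = 0.60) {
  frac <- frac_expressing(clones, dataset, gene)
  clones$cd8a_fraction <- frac
  clones$lineage <- ifelse(frac > threshold, "CD8", "CD4")
  clones
}

#' Classify CD4 clones as regulatory from Foxp3 expression
#'
#' A CD4 clone is a Treg clone when strictly more than `threshold` (default
#' 10%) of its member cells express `Foxp3` (raw count > 0). Calling this on a
#' CD8 clone is an error; use [classify_clones()] on mixed tables.
#'
#' @param clones CD4 clone tibble with a `lineage` column.
#' @param dataset the [tcell_dataset()].
#' @param gene Treg marker gene symbol.
#' @param threshold strict fraction above which the clone is called Treg.
#' @return `clones` with added `foxp3_fraction` and `is_treg` columns.
#' @export
classify_treg <- function(clones, dataset, gene = "Foxp3", threshold = 0.10) {
  if (!"lineage" %in% names(clones)) {
    stop("run classify_lineage() first", call. = FALSE)
  }
  if (any(clones$lineage != "CD4")) {
    stop("classify_treg() is defined for CD4 clones only", call. = FALSE)
  }
  frac <- frac_expressing(clones, dataset, gene)
  clones$foxp3_fraction <- frac
  clones$is_treg <- frac > threshold
  clones
}

#' Lineage + Treg classification for a mixed clone table
#'
#' Convenience wrapper: runs [classify_lineage()], then [classify_treg()] on
#' the CD4 subset; CD8 clones get `is_treg = FALSE`.
#'
#' @inheritParams classify_lineage
#' @param treg_gene,treg_threshold passed to [classify_treg()].
#' @return Annotated clone tibble (original order preserved).
#' @export
classify_clones <- function(clones, dataset, gene = "Cd8a", threshold = 0.60,
                            treg_gene = "Foxp3", treg_threshold = 0.10) {
  clones <- classify_lineage(clones, dataset, gene, threshold)
  cd4 <- clones$lineage == "CD4"
  clones$foxp3_fraction <- NA_real_
  clones$is_treg <- FALSE
  if (any(cd4)) {
    sub <- classify_treg(clones[cd4, ], dataset, treg_gene, treg_threshold)
    clones$foxp3_fraction[cd4] <- sub$foxp3_fraction
    clones$is_treg[cd4] <- sub$is_treg
  }
  clones
}

#' Per-tissue clone counts and frequencies
#'
#' Clone frequency in a tissue is the clone's cell count there divided by the
#' total number of captured T cells in that tissue compartment (all cells of
#' the dataset, expanded or not), so frequencies over all clones plus
#' unexpanded cells sum to 1 per tissue.
#'
#' @param clones clone tibble.
#' @param dataset the [tcell_dataset()]; `meta$tissue` must be populated.
#' @return `clones` with `n_<tissue>` and `freq_<tissue>` columns per tissue.
#' @export
clone_tissue_stats <- function(clones, dataset) {
  tissue <- dataset_tissues(dataset)
  tissues <- sort(unique(tissue))
  totals <- table(tissue)
  for (ts in tissues) {
    in_ts <- stats::setNames(tissue == ts, dataset$barcodes)
    n <- vapply(clones$barcodes, function(bc) sum(in_ts[bc]), numeric(1))
    clones[[paste0("n_", ts)]] <- as.integer(n)
    clones[[paste0("freq_", ts)]] <- n / as.numeric(totals[[ts]])
  }
  clones
}

dataset_tissues <- function(dataset) {
  if (!"tissue" %in% names(dataset$meta)) {
    stop("dataset meta has no 'tissue' column", call. = FALSE)
  }
  as.character(dataset$meta$tissue)
}

#' Frequency of each clone among captured T cells of one tissue
#'
#' @param clones clone tibble.
#' @param dataset the [tcell_dataset()].
#' @param tissue tissue name (must have at least one captured cell).
#' @return Numeric vector, one frequency per clone row.
#' @export
clone_frequency <- function(clones, dataset, tissue) {
  tiss <- dataset_tissues(dataset)
  total <- sum(tiss == tissue)
  if (total == 0) stop("no captured cells in tissue '", tissue, "'", call. = FALSE)
  in_ts <- stats::setNames(tiss == tissue, dataset$barcodes)
  vapply(clones$barcodes, function(bc) sum(in_ts[bc]), numeric(1)) / total
}

#' Filter clones by size and tumor presence
#'
#' Implements the expansion filter: keep clones of size strictly greater than
#' 15 (i.e. `size >= min_size` with the default `min_size = 16`) that have at
#' least one cell in `require_tissue`. An additional floor `size_ge` (75 for
#' trajectory clustering) can be stacked on top.
#'
#' @param clones clone tibble; per-tissue counts are computed from `dataset`
#'   if the `n_<tissue>` column is absent.
#' @param dataset the [tcell_dataset()] (needed when tissue counts are absent).
#' @param min_size minimum clone size kept (inclusive).
#' @param require_tissue tissue that must contain at least one member cell;
#'   `NULL` disables the presence requirement.
#' @param size_ge optional additional inclusive size floor.
#' @return The filtered clone tibble.
#' @export
filter_clones <- function(clones, dataset = NULL, min_size = 16,
                          require_tissue = "tumor", size_ge = NULL) {
  keep <- clones$size >= min_size
  if (!is.null(require_tissue)) {
    col <- paste0("n_", require_tissue)
    if (!col %in% names(clones)) {
      if (is.null(dataset)) {
        stop("clones lack '", col, "'; supply dataset to compute tissue counts",
             call. = FALSE)
      }
      if (!require_tissue %in% dataset_tissues(dataset)) {
        stop("unknown tissue '", require_tissue, "'", call. = FALSE)
      }
      clones <- clone_tissue_stats(clones, dataset)
    }
    keep <- keep & clones[[col]] >= 1
  }
  if (!is.null(size_ge)) keep <- keep & clones$size >= size_ge
  clones[keep, , drop = FALSE]
}

#' Spatial distribution bias of a clone
#'
#' Ratio of the clone's frequency in the lymphoid compartment (spleen) to its
#' frequency in the tumor. Tumor-confined clones (zero spleen frequency) get
#' 0; a clone with zero tumor frequency is an error (apply [filter_clones()]
#' with tumor presence first).
#'
#' @param clones clone tibble with `freq_<tissue>` columns (see
#'   [clone_tissue_stats()]).
#' @param spleen,tumor tissue names of the two compartments.
#' @return `clones` with an added `bias` column.
#' @export
spatial_distribution_bias <- function(clones, spleen = "spleen", tumor = "tumor") {
  fs <- clones[[paste0("freq_", spleen)]]
  ft <- clones[[paste0("freq_", tumor)]]
  if (is.null(fs) || is.null(ft)) {
    stop("run clone_tissue_stats() first", call. = FALSE)
  }
  if (any(ft == 0)) {
    stop("clone(s) with zero tumor frequency: ",
         paste(clones$clone_id[ft == 0], collapse = ", "), call. = FALSE)
  }
  clones$bias <- fs / ft
  clones
}

#' Fraction of clones whose TCR recurs in another repertoire
#'
#' @param clones_a clone tibble (non-empty).
#' @param repertoire_b a clone tibble or a character vector of sequences to
#'   match against.
#' @param key `"beta_nt"` (bulk-style beta-chain matching) or `"pair_nt"`
#'   (full alpha+beta pair).
#' @return Fraction of `clones_a` rows whose key is present in `repertoire_b`.
#' @export
repertoire_overlap <- function(clones_a, repertoire_b,
                               key = c("beta_nt", "pair_nt")) {
  key <- match.arg(key)
  if (nrow(clones_a) == 0) stop("clones_a is empty", call. = FALSE)
  keyify <- function(x) {
    if (is.character(x)) return(x)
    if (key == "beta_nt") x$beta_nt else paste(x$alpha_nt, x$beta_nt, sep = "|")
  }
  a <- keyify(clones_a)
  b <- keyify(repertoire_b)
  if (length(b) == 0) stop("repertoire_b is empty", call. = FALSE)
  mean(a %in% b)
}

#' Select the n largest clones by tumor frequency
#'
#' Ties are broken deterministically by ascending `clone_id`; if fewer than
#' `n` clones are supplied all are returned.
#'
#' @param clones clone tibble with a `freq_tumor` (or `freq_col`) column.
#' @param n number of clones to keep.
#' @param freq_col frequency column used for ranking.
#' @return The top-`n` clone tibble.
#' @export
top_n_by_tumor_frequency <- function(clones, n = 200, freq_col = "freq_tumor") {
  if (!freq_col %in% names(clones)) {
    stop("column '", freq_col, "' not found; run clone_tissue_stats() first",
         call. = FALSE)
  }
  ord <- order(-clones[[freq_col]], clones$clone_id)
  clones[ord[seq_len(min(n, nrow(clones)))], , drop = FALSE]
}

#' Clones with a minimum number of cells in every listed tissue
#'
#' Helper predicate for analyses that require representation in several
#' compartments (e.g. at least two member cells in both tumor and spleen).
#'
#' @param clones clone tibble with `n_<tissue>` columns.
#' @param tissues tissue names to require.
#' @param min_cells inclusive per-tissue floor.
#' @return Logical vector over clone rows.
#' @export
has_min_cells_per_tissue <- function(clones, tissues = c("tumor", "spleen"),
                                     min_cells = 2) {
  Reduce(`&`, lapply(tissues, function(ts) {
    col <- paste0("n_", ts)
    if (!col %in% names(clones)) stop("missing column ", col, call. = FALSE)
    clones[[col]] >= min_cells
  }))
}
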