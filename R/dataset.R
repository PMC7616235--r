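#' Paired expression/TCR dataset container
#'
#' Bundles a sparse cells-by-genes count matrix with per-cell metadata, an
#' optional per-cell TCR chain-pair table, and named transformed layers
#' (e.g. `"lognorm"`). All per-cell tables are keyed by barcode and kept in
#' the row order of the count matrix.
#'
#' @param counts sparse (or dense) non-negative integer matrix, cells in rows,
#'   genes in columns. Coerced to `Matrix::dgCMatrix`.
#' @param gene_ids character vector of gene symbols, one per column.
#' @param barcodes character vector of unique cell barcodes, one per row.
#' @param meta optional tibble of per-cell metadata with a `barcode` column
#'   (typical columns: `tissue`, `animal_id`, `fatemap_label`).
#' @param tcr optional tibble of per-cell TCR chain pairs as returned by
#'   [read_tcr_table()] (one row per barcode, `complete` flag).
#' @param layers named list of matrices with the same shape as `counts`.
#'
#' @return An object of class `tcell_dataset`.
#' @export
tcell_dataset <- function(counts, gene_ids, barcodes, meta = NULL, tcr = NULL,
                          layers = list()) {
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (nrow(counts) != length(barcodes)) {
    stop("dimension mismatch: ", nrow(counts), " matrix rows but ",
         length(barcodes), " barcodes", call. = FALSE)
  }
  if (ncol(counts) != length(gene_ids)) {
    stop("dimension mismatch: ", ncol(counts), " matrix columns but ",
         length(gene_ids), " gene ids", call. = FALSE)
  }
  if (anyDuplicated(barcodes)) {
    stop("barcodes must be unique", call. = FALSE)
  }
  x <- counts@x
  if (length(x) && (any(x < 0) || any(x != round(x)))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  dimnames(counts) <- list(barcodes, gene_ids)
  if (is.null(meta)) {
    meta <- tibble::tibble(barcode = barcodes)
  } else {
    meta <- tibble::as_tibble(meta)
    if (!"barcode" %in% names(meta)) stop("meta must have a 'barcode' column", call. = FALSE)
    if (!setequal(meta$barcode, barcodes)) {
      stop("meta barcodes do not match matrix barcodes", call. = FALSE)
    }
    meta <- meta[match(barcodes, meta$barcode), ]
  }
  if (!is.null(tcr)) {
    tcr <- tibble::as_tibble(tcr)
    tcr <- tcr[tcr$barcode %in% barcodes, ]
  }
  structure(
    list(counts = counts, gene_ids = gene_ids, barcodes = barcodes,
         meta = meta, tcr = tcr, layers = layers),
    class = "tcell_dataset"
  )
}

#' @exportS3Method base::print
print.tcell_dataset <- function(x, ...) {
  cat("<tcell_dataset> ", length(x$barcodes), " cells x ", length(x$gene_ids),
      " genes\n", sep = "")
  if (!is.null(x$tcr)) {
    cat("  TCR table: ", nrow(x$tcr), " cells (",
        sum(x$tcr$complete), " complete pairs)\n", sep = "")
  }
  if (length(x$layers)) cat("  layers:", paste(names(x$layers), collapse = ", "), "\n")
  if ("tissue" %in% names(x$meta)) {
    tab <- table(x$meta$tissue)
    cat("  tissues:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @exportS3Method base::dim
dim.tcell_dataset <- function(x) dim(x$counts)

#' Subset a dataset to a set of cells and/or genes
#'
#' Layers, metadata and the TCR table are subset consistently.
#'
#' @param dataset a [tcell_dataset()].
#' @param cells logical/integer/character index of cells to keep.
#' @param genes logical/integer/character index of genes to keep.
#' @return A `tcell_dataset`.
#' @export
subset_dataset <- function(dataset, cells = NULL, genes = NULL) {
  stopifnot(inherits(dataset, "tcell_dataset"))
  if (is.null(cells)) cells <- seq_along(dataset$barcodes)
  if (is.null(genes)) genes <- seq_along(dataset$gene_ids)
  counts <- dataset$counts[cells, genes, drop = FALSE]
  layers <- lapply(dataset$layers, function(m) m[cells, genes, drop = FALSE])
  bc <- rownames(counts)
  tcr <- dataset$tcr
  if (!is.null(tcr)) tcr <- tcr[match(bc, tcr$barcode), , drop = FALSE]
  out <- tcell_dataset(counts, colnames(counts), bc,
                       meta = dataset$meta[match(bc, dataset$meta$barcode), ],
                       tcr = tcr)
  out$layers <- layers
  out
}

#' Barcodes of cells belonging to a clone
#'
#' @param clones clone tibble (one or more rows) with a `barcodes` list-column.
#' @return Character vector of member barcodes.
#' @keywords internal
clone_barcodes <- function(clones) unlist(clones$barcodes, use.names = FALSE)
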