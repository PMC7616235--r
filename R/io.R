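#' Read a sparse count matrix with gene/barcode sidecar files
#'
#' Reads the standard triplet layout (matrix-market `.mtx` plus line-per-entry
#' `genes.tsv` / `barcodes.tsv`). Orientation is inferred from the sidecar
#' lengths: genes-in-rows (the 10x convention) is transposed to the package's
#' cells-by-genes layout.
#'
#' @param matrix_path path to the `.mtx` file.
#' @param genes_path path to the gene sidecar (first tab field used as symbol).
#' @param barcodes_path path to the barcode sidecar.
#' @return A [tcell_dataset()] with raw counts only.
#' @export
read_counts <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  m <- Matrix::readMM(matrix_path)
  genes <- readr::read_tsv(genes_path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)[[1]]
  barcodes <- readr::read_lines(barcodes_path, progress = FALSE)
  barcodes <- barcodes[nzchar(barcodes)]
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in ", barcodes_path, call. = FALSE)
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                       # 10x convention: genes x cells
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(genes))) {
    stop("dimension mismatch: matrix is ", nrow(m), " x ", ncol(m),
         " but sidecars give ", length(genes), " genes and ",
         length(barcodes), " barcodes", call. = FALSE)
  }
  tcell_dataset(m, genes, barcodes)
}

#' Write a dataset's counts in the triplet layout read by [read_counts()]
#'
#' @param dataset a [tcell_dataset()].
#' @param dir output directory (created if missing). Writes `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv` in the genes-by-cells (10x) orientation.
#' @return `dir`, invisibly.
#' @export
write_counts <- function(dataset, dir) {
  stopifnot(inherits(dataset, "tcell_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::t(dataset$counts), file.path(dir, "matrix.mtx"))
  readr::write_lines(dataset$gene_ids, file.path(dir, "genes.tsv"))
  readr::write_lines(dataset$barcodes, file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

contig_csv_cols <- c("barcode", "contig_id", "chain", "v_gene", "j_gene",
                     "cdr3", "cdr3_nt", "productive", "umis")
airr_tsv_cols <- c("cell_id", "locus", "productive", "sequence",
                   "junction_aa", "v_call", "j_call", "duplicate_count")

#' Read per-cell TCR chain pairs from a contig table
#'
#' Parses either the 10x `filtered_contig_annotations.csv` column dialect or an
#' AIRR Rearrangement TSV and collapses contigs to at most one alpha and one
#' beta chain per barcode. For a barcode with several productive contigs of the
#' same chain the highest-UMI contig wins, ties broken lexicographically by
#' contig id. Cells lacking either chain get `complete = FALSE`.
#'
#' For the contig CSV dialect the full-length `sequence` column is used as the
#' V(D)J nucleotide identity when present, `cdr3_nt` otherwise.
#'
#' @param path table path.
#' @param dialect `"contig_csv"` or `"airr_tsv"`.
#' @return A tibble with one row per barcode: `barcode`, `alpha_nt`, `beta_nt`,
#'   `alpha_cdr3_aa`, `beta_cdr3_aa`, `alpha_v`, `alpha_j`, `beta_v`, `beta_j`,
#'   `complete`.
#' @export
read_tcr_table <- function(path, dialect = c("contig_csv", "airr_tsv")) {
  dialect <- tryCatch(match.arg(dialect),
                      error = function(e) stop("unknown dialect", call. = FALSE))
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (dialect == "contig_csv") {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(contig_csv_cols, names(tab))
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    contigs <- tibble::tibble(
      barcode = as.character(tab$barcode),
      contig_id = as.character(tab$contig_id),
      chain = as.character(tab$chain),
      nt = as.character(if ("sequence" %in% names(tab)) tab$sequence else tab$cdr3_nt),
      cdr3_aa = as.character(tab$cdr3),
      v_gene = as.character(tab$v_gene),
      j_gene = as.character(tab$j_gene),
      productive = tolower(as.character(tab$productive)) %in% c("true", "t", "yes"),
      umis = as.numeric(tab$umis)
    )
  } else {
    tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    missing <- setdiff(airr_tsv_cols, names(tab))
    if (length(missing)) {
      stop("missing required column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    contigs <- tibble::tibble(
      barcode = as.character(tab$cell_id),
      contig_id = as.character(
        if ("sequence_id" %in% names(tab)) tab$sequence_id else seq_len(nrow(tab))),
      chain = as.character(tab$locus),
      nt = as.character(tab$sequence),
      cdr3_aa = as.character(tab$junction_aa),
      v_gene = as.character(tab$v_call),
      j_gene = as.character(tab$j_call),
      productive = tolower(as.character(tab$productive)) %in% c("true", "t", "yes"),
      umis = as.numeric(tab$duplicate_count)
    )
  }
  contigs <- contigs[contigs$productive & contigs$chain %in% c("TRA", "TRB") &
                       !is.na(contigs$nt) & nzchar(contigs$nt), ]
  best <- contigs |>
    dplyr::arrange(.data$barcode, .data$chain,
                   dplyr::desc(.data$umis), .data$contig_id) |>
    dplyr::distinct(.data$barcode, .data$chain, .keep_all = TRUE)
  wide <- function(ch, col) {
    sub <- best[best$chain == ch, ]
    stats::setNames(sub[[col]], sub$barcode)
  }
  all_bc <- sort(unique(contigs$barcode))
  a_nt <- wide("TRA", "nt"); b_nt <- wide("TRB", "nt")
  out <- tibble::tibble(
    barcode = all_bc,
    alpha_nt = unname(a_nt[all_bc]),
    beta_nt = unname(b_nt[all_bc]),
    alpha_cdr3_aa = unname(wide("TRA", "cdr3_aa")[all_bc]),
    beta_cdr3_aa = unname(wide("TRB", "cdr3_aa")[all_bc]),
    alpha_v = unname(wide("TRA", "v_gene")[all_bc]),
    alpha_j = unname(wide("TRA", "j_gene")[all_bc]),
    beta_v = unname(wide("TRB", "v_gene")[all_bc]),
    beta_j = unname(wide("TRB", "j_gene")[all_bc])
  )
  out$complete <- !is.na(out$alpha_nt) & nzchar(out$alpha_nt) &
    !is.na(out$beta_nt) & nzchar(out$beta_nt)
  out
}

#' Quality-control filter for cells
#'
#' Keeps cells with a detected-feature count inside `[min_features,
#' max_features]` (inclusive), a mitochondrial count fraction strictly below
#' `max_mito_fraction`, and (optionally) a complete, productive alpha+beta TCR
#' chain pair. Per-criterion removal counts are attached as the `"qc_report"`
#' attribute and can be retrieved with [qc_report()].
#'
#' @param dataset a [tcell_dataset()].
#' @param min_features,max_features inclusive bounds on genes detected per cell.
#' @param max_mito_fraction strict upper bound on mitochondrial fraction.
#' @param require_complete_tcr keep only cells with `complete == TRUE` in the
#'   TCR table (errors if no TCR table is attached).
#' @param mito_prefix gene-symbol prefix identifying mitochondrial genes
#'   (case-insensitive; default the mouse `"mt-"`).
#' @return The filtered `tcell_dataset`.
#' @export
qc_filter <- function(dataset, min_features = 200, max_features = 5000,
                      max_mito_fraction = 0.10, require_complete_tcr = TRUE,
                      mito_prefix = "mt-") {
  stopifnot(inherits(dataset, "tcell_dataset"))
  n_feat <- Matrix::rowSums(dataset$counts > 0)
  total <- Matrix::rowSums(dataset$counts)
  mito_genes <- startsWith(tolower(dataset$gene_ids), tolower(mito_prefix))
  mito <- if (any(mito_genes)) {
    Matrix::rowSums(dataset$counts[, mito_genes, drop = FALSE])
  } else rep(0, length(total))
  mito_frac <- ifelse(total > 0, mito / total, 0)
  pass_feat <- n_feat >= min_features & n_feat <= max_features
  pass_mito <- mito_frac < max_mito_fraction
  if (require_complete_tcr) {
    if (is.null(dataset$tcr)) {
      stop("require_complete_tcr = TRUE but no TCR table is attached", call. = FALSE)
    }
    complete_bc <- dataset$tcr$barcode[dataset$tcr$complete]
    pass_tcr <- dataset$barcodes %in% complete_bc
  } else {
    pass_tcr <- rep(TRUE, length(total))
  }
  keep <- pass_feat & pass_mito & pass_tcr
  if (!any(keep)) stop("qc_filter removed all cells", call. = FALSE)
  report <- list(
    n_input = length(keep),
    n_kept = sum(keep),
    removed_features = sum(!pass_feat),
    removed_mito = sum(!pass_mito),
    removed_tcr = sum(!pass_tcr),
    params = list(min_features = min_features, max_features = max_features,
                  max_mito_fraction = max_mito_fraction,
                  require_complete_tcr = require_complete_tcr,
                  mito_prefix = mito_prefix)
  )
  out <- subset_dataset(dataset, cells = which(keep))
  attr(out, "qc_report") <- report
  out
}

#' Retrieve the QC report attached by [qc_filter()]
#' @param dataset a filtered `tcell_dataset`.
#' @return A list of per-criterion removal counts and parameters.
#' @export
qc_report <- function(dataset) attr(dataset, "qc_report")

#' Remove variable TCR genes from the expression matrix
#'
#' Drops every gene whose symbol contains `"TRAV"` or `"TRBV"`
#' (case-insensitive substring, covering mouse `Trav`/`Trbv` and human
#' `TRAV`/`TRBV` nomenclature) so that the rearranged receptor does not drive
#' downstream embeddings. All other genes keep their order.
#'
#' @param dataset a [tcell_dataset()].
#' @param patterns substrings flagging a gene for removal.
#' @return A `tcell_dataset` without the matching genes.
#' @export
drop_tcr_variable_genes <- function(dataset, patterns = c("trav", "trbv")) {
  stopifnot(inherits(dataset, "tcell_dataset"))
  lower <- tolower(dataset$gene_ids)
  hit <- Reduce(`|`, lapply(tolower(patterns), function(p) {
    stringr::str_detect(lower, stringr::fixed(p))
  }))
  if (!any(hit)) return(dataset)
  subset_dataset(dataset, genes = which(!hit))
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then gene symbols. Duplicate genes within a line are dropped with a warning.
#'
#' @param path GMT file path.
#' @return A named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- list()
  for (ln in lines) {
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line (need name, description, >=1 gene): ",
           substr(ln, 1, 40), call. = FALSE)
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicate genes in gene set '", fields[1], "' deduplicated",
              call. = FALSE)
      genes <- unique(genes)
    }
    out[[fields[1]]] <- genes
  }
  out
}

#' Write gene sets to a GMT file
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gene_sets, path, description = "clonetraj") {
  lines <- vapply(names(gene_sets), function(nm) {
    paste(c(nm, description, gene_sets[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
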