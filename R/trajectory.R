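#' Principal-component embedding of cells
#'
#' Centered PCA on the log-normalized layer (all genes by default, or a
#' supplied highly-variable subset). A deterministic sign convention is
#' applied: within each component the loading of largest magnitude is made
#' positive, so embeddings are reproducible across platforms.
#'
#' @param dataset dataset with a lognorm layer and TR-V genes removed.
#' @param n_dims number of components kept (default 50).
#' @param genes optional gene subset to embed on.
#' @return A `cell_embedding` object: `coords` (cells x n_dims matrix with
#'   barcode rownames), `var_explained`, `method = "pca"`.
#' @export
embed_pca <- function(dataset, n_dims = 50, genes = NULL) {
  ln <- get_layer(dataset)
  if (!is.null(genes)) ln <- ln[, genes, drop = FALSE]
  n_dims <- as.integer(n_dims)
  if (n_dims > min(dim(ln))) {
    stop("n_dims exceeds min(cells, genes)", call. = FALSE)
  }
  x <- as.matrix(ln)
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_dims)
  rot <- pc$rotation
  flip <- vapply(seq_len(ncol(rot)), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x[, seq_len(n_dims), drop = FALSE], 2, flip, `*`)
  rownames(coords) <- rownames(x)
  var <- pc$sdev^2
  structure(list(coords = coords,
                 var_explained = var[seq_len(n_dims)] / sum(var),
                 method = "pca"),
            class = "cell_embedding")
}

#' @exportS3Method base::print
print.cell_embedding <- function(x, ...) {
  cat("<cell_embedding> ", nrow(x$coords), " cells x ", ncol(x$coords),
      " dims (", x$method, ")\n", sep = "")
  invisible(x)
}

embedding_coords <- function(embedding) {
  if (inherits(embedding, "cell_embedding")) embedding$coords
  else as.matrix(embedding)
}

# k nearest neighbours computed blockwise to avoid an n x n distance matrix
knn_index <- function(coords, k, block = 512L) {
  n <- nrow(coords)
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  sq <- rowSums(coords^2)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    d2 <- outer(sq[rows], sq, "+") - 2 * coords[rows, , drop = FALSE] %*% t(coords)
    d2[cbind(seq_along(rows), rows)] <- Inf
    for (r in seq_along(rows)) {
      o <- order(d2[r, ])[seq_len(k)]
      idx[rows[r], ] <- o
      dst[rows[r], ] <- sqrt(pmax(d2[r, o], 0))
    }
  }
  list(index = idx, dist = dst)
}

#' Graph-distance pseudotime from a root cell
#'
#' Builds a symmetrized (union) k-nearest-neighbour graph over the embedding
#' with Euclidean edge weights and takes the shortest-path distance from the
#' root cell, min-max scaled to [0, 1]. This is a light-weight geodesic
#' stand-in for a full trajectory-inference run; an externally computed
#' pseudotime can be supplied through [import_pseudotime()] instead and takes
#' precedence in the pipeline when provided.
#'
#' @param embedding a `cell_embedding` (or a coordinate matrix with barcode
#'   rownames).
#' @param root_cell barcode of the root (pseudotime 0).
#' @param k_neighbors neighbours per cell.
#' @param connect_components if the kNN graph is disconnected, bridge
#'   components with their single shortest connecting edge instead of
#'   erroring (default `FALSE`: a disconnected graph is an error suggesting a
#'   larger `k_neighbors`).
#' @return A `pseudotime` tibble: `barcode`, `pseudotime`, with attributes
#'   `root_cell` and `method`.
#' @export
compute_pseudotime <- function(embedding, root_cell, k_neighbors = 15,
                               connect_components = FALSE) {
  coords <- embedding_coords(embedding)
  bc <- rownames(coords)
  if (is.null(bc)) stop("embedding must carry barcode rownames", call. = FALSE)
  if (!root_cell %in% bc) stop("root cell '", root_cell, "' not found", call. = FALSE)
  n <- nrow(coords)
  k <- min(k_neighbors, n - 1L)
  nn <- knn_index(coords, k)
  edges <- cbind(rep(seq_len(n), each = k), as.vector(t(nn$index)))
  w <- as.vector(t(nn$dist))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::E(g)$weight <- w
  g <- igraph::simplify(g, edge.attr.comb = list(weight = "min"))
  comp <- igraph::components(g)
  if (comp$no > 1) {
    if (!connect_components) {
      stop("kNN graph is disconnected (", comp$no, " components); raise ",
           "k_neighbors or set connect_components = TRUE", call. = FALSE)
    }
    g <- bridge_components(g, coords)
  }
  d <- as.numeric(igraph::distances(g, v = match(root_cell, bc),
                                    weights = igraph::E(g)$weight))
  pt <- (d - min(d)) / (max(d) - min(d))
  out <- tibble::tibble(barcode = bc, pseudotime = pt)
  attr(out, "root_cell") <- root_cell
  attr(out, "method") <- "diffusion"
  out
}

# repeatedly join the smallest component to the rest by the single shortest
# inter-component edge (Euclidean in embedding space)
bridge_components <- function(g, coords) {
  repeat {
    comp <- igraph::components(g)
    if (comp$no == 1) return(g)
    sizes <- comp$csize
    small <- which.min(sizes)
    a <- which(comp$membership == small)
    b <- which(comp$membership != small)
    ca <- coords[a, , drop = FALSE]
    cb <- coords[b, , drop = FALSE]
    d2 <- outer(rowSums(ca^2), rowSums(cb^2), "+") - 2 * ca %*% t(cb)
    hit <- arrayInd(which.min(d2), dim(d2))
    g <- igraph::add_edges(g, c(a[hit[1]], b[hit[2]]),
                           weight = sqrt(max(d2[hit], 0)))
  }
}

#' Import an externally computed pseudotime
#'
#' @param table tibble/data.frame with `barcode` and a numeric pseudotime
#'   column (second column used), or a named numeric vector.
#' @param barcodes optional barcodes that must all be covered (missing ones
#'   are an error).
#' @return A `pseudotime` tibble min-max scaled to [0, 1].
#' @export
import_pseudotime <- function(table, barcodes = NULL) {
  if (is.numeric(table) && !is.null(names(table))) {
    table <- tibble::tibble(barcode = names(table), pseudotime = unname(table))
  }
  table <- tibble::as_tibble(table)
  v <- as.numeric(table[[2]])
  bc <- as.character(table[[1]])
  if (!is.null(barcodes)) {
    miss <- setdiff(barcodes, bc)
    if (length(miss)) {
      stop(length(miss), " barcode(s) missing from pseudotime table", call. = FALSE)
    }
    keep <- match(barcodes, bc)
    bc <- bc[keep]; v <- v[keep]
  }
  if (any(!is.finite(v))) stop("non-finite pseudotime values", call. = FALSE)
  rng <- range(v)
  if (rng[1] == rng[2]) stop("pseudotime has zero range", call. = FALSE)
  out <- tibble::tibble(barcode = bc, pseudotime = (v - rng[1]) / diff(rng))
  attr(out, "root_cell") <- bc[which.min(v)]
  attr(out, "method") <- "external"
  out
}

#' Select a root cell by a naive/progenitor gene program
#'
#' Convenience root picker: the cell with the highest mean log-normalized
#' expression of a progenitor gene set (the simulator's shared early program,
#' or e.g. Tcf7/Sell/Ccr7 on real data).
#'
#' @param dataset dataset with a lognorm layer.
#' @param genes progenitor gene symbols.
#' @return The root cell's barcode.
#' @export
select_root_cell <- function(dataset, genes) {
  ln <- get_layer(dataset)
  present <- intersect(genes, colnames(ln))
  if (!length(present)) stop("no root-program gene present", call. = FALSE)
  m <- Matrix::rowSums(ln[, present, drop = FALSE]) / length(present)
  dataset$barcodes[which.max(m)]
}

#' Resampled per-clone trajectory through the embedding
#'
#' Member cells are ordered by pseudotime (normalized to the clone's own
#' [min, max] span); coordinates at tied pseudotimes are averaged; an optional
#' moving-average smoother (window 0.1 on the clone-normalized axis) damps
#' single-cell noise; finally each of the first `D_use` embedding dimensions
#' is linearly interpolated onto `L` equally spaced grid points. The grid is
#' invariant to cell order and to affine rescaling of pseudotime.
#'
#' @param barcodes member cell barcodes (or a one-row clone tibble).
#' @param embedding a `cell_embedding` or coordinate matrix.
#' @param pseudotime a `pseudotime` tibble.
#' @param L grid length.
#' @param D_use number of leading embedding dimensions used.
#' @param smooth apply the moving-average smoother.
#' @param window smoother window on the clone-normalized pseudotime axis.
#' @param clone_id id stored on the result.
#' @return A `clone_trajectory`: list(`clone_id`, `grid` L x D_use matrix,
#'   `n_cells`, `pseudotime_span`).
#' @export
build_clone_trajectory <- function(barcodes, embedding, pseudotime, L = 20,
                                   D_use = 10, smooth = TRUE, window = 0.1,
                                   clone_id = NULL) {
  if (is.data.frame(barcodes)) {
    if (is.null(clone_id)) clone_id <- barcodes$clone_id[[1]]
    barcodes <- barcodes$barcodes[[1]]
  }
  coords <- embedding_coords(embedding)
  D_use <- min(D_use, ncol(coords))
  pt <- stats::setNames(pseudotime$pseudotime, pseudotime$barcode)[barcodes]
  if (anyNA(pt)) stop("member cell(s) missing from pseudotime", call. = FALSE)
  span <- range(pt)
  if (diff(span) == 0) {
    stop("all member cells at identical pseudotime", call. = FALSE)
  }
  t_norm <- (pt - span[1]) / diff(span)
  x <- coords[barcodes, seq_len(D_use), drop = FALSE]
  # average coordinates at tied pseudotimes, then order
  ord <- order(t_norm)
  t_o <- t_norm[ord]
  x_o <- x[ord, , drop = FALSE]
  grp <- cumsum(!duplicated(t_o))
  t_u <- tapply(t_o, grp, function(v) v[1])
  x_u <- apply(x_o, 2, function(col) tapply(col, grp, mean))
  x_u <- matrix(x_u, nrow = length(t_u))
  if (smooth && length(t_u) > 2) {
    half <- window / 2
    x_s <- x_u
    for (i in seq_along(t_u)) {
      w <- abs(t_u - t_u[i]) <= half
      x_s[i, ] <- colMeans(x_u[w, , drop = FALSE])
    }
    x_u <- x_s
  }
  grid_t <- seq(0, 1, length.out = L)
  grid <- vapply(seq_len(D_use), function(j) {
    if (length(t_u) == 1) rep(x_u[1, j], L)
    else stats::approx(t_u, x_u[, j], xout = grid_t, rule = 2)$y
  }, numeric(L))
  structure(list(clone_id = clone_id, grid = grid,
                 n_cells = length(barcodes), pseudotime_span = span),
            class = "clone_trajectory")
}

#' Trajectories for every clone in a table
#'
#' @param clones clone tibble (apply the size >= 75 floor with
#'   [filter_clones()] first for trajectory clustering).
#' @inheritParams build_clone_trajectory
#' @return A named list of `clone_trajectory` objects (class
#'   `trajectory_set`).
#' @export
build_clone_trajectories <- function(clones, embedding, pseudotime, L = 20,
                                     D_use = 10, smooth = TRUE, window = 0.1) {
  out <- purrr::map(seq_len(nrow(clones)), function(i) {
    build_clone_trajectory(clones$barcodes[[i]], embedding, pseudotime,
                           L = L, D_use = D_use, smooth = smooth,
                           window = window, clone_id = clones$clone_id[[i]])
  })
  names(out) <- clones$clone_id
  class(out) <- "trajectory_set"
  out
}

#' @exportS3Method base::print
print.trajectory_set <- function(x, ...) {
  L <- nrow(x[[1]]$grid); D <- ncol(x[[1]]$grid)
  cat("<trajectory_set> ", length(x), " clones, grid ", L, " x ", D, "\n",
      sep = "")
  invisible(x)
}

#' Long-format tibble of a trajectory set
#' @param x a `trajectory_set`.
#' @param ... unused.
#' @return Tibble: `clone_id`, `point`, `t`, `dim`, `value`.
#' @exportS3Method generics::tidy
#' @export
tidy.trajectory_set <- function(x, ...) {
  purrr::map_dfr(x, function(tr) {
    L <- nrow(tr$grid); D <- ncol(tr$grid)
    tibble::tibble(
      clone_id = tr$clone_id,
      point = rep(seq_len(L), D),
      t = rep(seq(0, 1, length.out = L), D),
      dim = rep(seq_len(D), each = L),
      value = as.vector(tr$grid)
    )
  })
}
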