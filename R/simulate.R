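#' Specification of one clonal differentiation pattern
#'
#' A pattern is a path through a latent program-activity space together with
#' an occupancy density over the progression variable u in [0, 1]: the path
#' says *where* a clone's cells differentiate to, the occupancy says *how*
#' the clone's cells are distributed along that path. Cells are placed on the
#' path at positions drawn from the occupancy, so two patterns can share a
#' path (hence a centroid) while occupying it very differently.
#'
#' @param name pattern name.
#' @param anchors numeric matrix (n_anchors x n_programs) of program
#'   activities at the anchor progressions; activities between anchors are
#'   linearly interpolated.
#' @param anchor_u increasing progression values of the anchors (first 0,
#'   last 1).
#' @param occupancy tibble/data.frame with columns `mean`, `sd`, `weight`
#'   describing a mixture of normals truncated to [0, 1] (weights must sum
#'   to 1).
#' @param tissue_split numeric `c(intercept, slope)`: a cell at progression u
#'   is placed in the tumor with probability
#'   `clamp(intercept + slope * u, 0.02, 0.98)`, in the spleen otherwise.
#' @param cd8 does the pattern carry the CD8 lineage marker?
#' @param treg for CD4 patterns, is the Treg marker expressed?
#' @return A `pattern_spec` list.
#' @export
pattern_spec <- function(name, anchors, anchor_u, occupancy,
                         tissue_split = c(0.15, 0.7), cd8 = TRUE,
                         treg = FALSE) {
  anchors <- as.matrix(anchors)
  occupancy <- tibble::as_tibble(occupancy)
  stopifnot(nrow(anchors) >= 2, nrow(anchors) == length(anchor_u),
            all(diff(anchor_u) > 0),
            all(c("mean", "sd", "weight") %in% names(occupancy)))
  if (abs(sum(occupancy$weight) - 1) > 1e-8) {
    stop("occupancy weights must sum to 1", call. = FALSE)
  }
  structure(list(name = name, anchors = anchors, anchor_u = anchor_u,
                 occupancy = occupancy, tissue_split = tissue_split,
                 cd8 = cd8, treg = treg),
            class = "pattern_spec")
}

#' Whole-dataset simulation configuration
#'
#' @param patterns list of [pattern_spec()]s (all with the same program
#'   count).
#' @param clones_per_pattern clones simulated per pattern.
#' @param cells_per_clone integer range `c(lo, hi)`; clone sizes are uniform
#'   on it.
#' @param n_genes total genes (lineage + mitochondrial + TR-V decoys +
#'   program markers + background).
#' @param n_marker_genes_per_program marker genes per latent program.
#' @param marker_loading log-scale loading of a marker on its program.
#' @param nb_dispersion negative-binomial dispersion (Var = mu + disp * mu^2).
#' @param library_sdlog sd(log) of the per-cell library-size factor.
#' @param marker_baseline,background_baseline `c(meanlog, sdlog)` of the
#'   log-normal baseline mean expression for marker / background genes.
#' @param lineage_means mean counts of Cd8a and Foxp3 in positive/negative
#'   lineages.
#' @param modules optional list of scorable state modules (see
#'   [simulate_scorable_states()]).
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(patterns, clones_per_pattern = 12,
                              cells_per_clone = c(75, 150), n_genes = 300,
                              n_marker_genes_per_program = 15,
                              marker_loading = 1.0, nb_dispersion = 0.3,
                              library_sdlog = 0.15,
                              marker_baseline = c(log(2), 0.5),
                              background_baseline = c(log(1.2), 0.8),
                              lineage_means = list(cd8a_pos = 3, cd8a_neg = 0.05,
                                                   foxp3_pos = 1, foxp3_neg = 0.01),
                              modules = list()) {
  n_programs <- ncol(patterns[[1]]$anchors)
  stopifnot(length(patterns) >= 1,
            all(vapply(patterns, function(p) ncol(p$anchors), 0L) == n_programs),
            clones_per_pattern >= 1, all(cells_per_clone >= 1),
            n_genes > n_programs * n_marker_genes_per_program + 10,
            nb_dispersion > 0)
  structure(list(patterns = patterns, clones_per_pattern = clones_per_pattern,
                 cells_per_clone = cells_per_clone, n_genes = n_genes,
                 n_programs = n_programs,
                 n_marker_genes_per_program = n_marker_genes_per_program,
                 marker_loading = marker_loading,
                 nb_dispersion = nb_dispersion,
                 library_sdlog = library_sdlog,
                 marker_baseline = marker_baseline,
                 background_baseline = background_baseline,
                 lineage_means = lineage_means, modules = modules),
            class = "simulation_config")
}

#' The default five-pattern benchmark configuration
#'
#' Five differentiation patterns over 8 latent programs. Four of them live on
#' one shared differentiation axis (program 1, the effector program, with
#' activity rising 0 to 2.5 over progression u; program 8 is a shared naive
#' program with activity 2 (1 - u), anchoring a common early state at u = 0)
#' and differ only in how their cells occupy that axis; the fifth departs
#' from the axis midpoint into a separate branch program:
#' \describe{
#'   \item{early_confined}{occupancy N(0.15, 0.10) — cells stay early}
#'   \item{late_confined}{occupancy N(0.85, 0.10) — cells pile up late}
#'   \item{bimodal}{occupancy half N(0.1, 0.06), half N(0.9, 0.06) — the
#'     clone straddles both ends}
#'   \item{unimodal_middle}{occupancy N(0.5, 0.06) — cells sit mid-axis}
#'   \item{branch}{path turns into program 4 at u = 0.5; broad occupancy
#'     N(0.5, 0.3); CD4 identity}
#' }
#' `bimodal` and `unimodal_middle` are the confounded pair: they share the
#' same straight path and both have mean progression 1/2, so their expected
#' expression centroids are identical (and both are CD8), yet their
#' trajectories differ (full-span traverse vs middle-confined segment).
#' First-moment (centroid) clustering cannot separate them; trajectory
#' clustering can.
#'
#' @param clones_per_pattern,cells_per_clone,nb_dispersion,library_sdlog
#'   overrides of the corresponding [simulation_config()] fields.
#' @return A `simulation_config` with 5 patterns.
#' @export
default_five_pattern_config <- function(clones_per_pattern = 12,
                                        cells_per_clone = c(75, 150),
                                        nb_dispersion = 0.3,
                                        library_sdlog = 0.15) {
  P <- 8; amp <- 2.5; naive <- 2; leg <- 1.5
  line1 <- matrix(0, 2, P)
  line1[2, 1] <- amp
  line1[1, P] <- naive          # program 8: shared naive, decays to 0
  branch <- matrix(0, 3, P)
  branch[1, P] <- naive
  branch[2, 1] <- amp / 2; branch[2, P] <- naive / 2
  branch[3, 1] <- amp / 2; branch[3, 4] <- leg
  occ <- function(mean, sd, weight = 1) tibble::tibble(mean = mean, sd = sd,
                                                       weight = weight)
  patterns <- list(
    pattern_spec("early_confined", line1, c(0, 1), occ(0.15, 0.10)),
    pattern_spec("late_confined", line1, c(0, 1), occ(0.85, 0.10)),
    pattern_spec("bimodal", line1, c(0, 1),
                 occ(c(0.1, 0.9), c(0.06, 0.06), c(0.5, 0.5))),
    pattern_spec("unimodal_middle", line1, c(0, 1), occ(0.5, 0.06)),
    pattern_spec("branch", branch, c(0, 0.5, 1), occ(0.5, 0.30), cd8 = FALSE)
  )
  simulation_config(patterns, clones_per_pattern = clones_per_pattern,
                    cells_per_clone = cells_per_clone,
                    nb_dispersion = nb_dispersion,
                    library_sdlog = library_sdlog)
}

# mixture of [0,1]-truncated normals -------------------------------------

rtrunc_mixture <- function(n, occupancy) {
  comp <- sample.int(nrow(occupancy), n, replace = TRUE,
                     prob = occupancy$weight)
  m <- occupancy$mean[comp]; s <- occupancy$sd[comp]
  lo <- stats::pnorm(0, m, s); hi <- stats::pnorm(1, m, s)
  stats::qnorm(stats::runif(n, lo, hi), m, s)
}

#' Occupancy density of a pattern over u
#' @param pattern a [pattern_spec()].
#' @param u progression values.
#' @return Density values.
#' @export
occupancy_density <- function(pattern, u) {
  occ <- pattern$occupancy
  rowSums(vapply(seq_len(nrow(occ)), function(k) {
    m <- occ$mean[k]; s <- occ$sd[k]
    z <- stats::pnorm(1, m, s) - stats::pnorm(0, m, s)
    occ$weight[k] * ifelse(u >= 0 & u <= 1, stats::dnorm(u, m, s) / z, 0)
  }, numeric(length(u))))
}

pattern_activity <- function(pattern, u) {
  vapply(seq_len(ncol(pattern$anchors)), function(p) {
    stats::approx(pattern$anchor_u, pattern$anchors[, p], xout = u,
                  rule = 2)$y
  }, numeric(length(u)))
}

#' Expected program-activity centroid of a pattern
#'
#' Numerically integrates the path position against the occupancy density —
#' the first moment a centroid-based clone comparison sees (up to the linear
#' gene-space map). Used to verify the confounded pair.
#'
#' @param pattern a [pattern_spec()].
#' @return Numeric vector of expected activities, one per program.
#' @export
expected_activity <- function(pattern) {
  vapply(seq_len(ncol(pattern$anchors)), function(p) {
    stats::integrate(function(u) {
      pattern_activity(pattern, u)[, p] * occupancy_density(pattern, u)
    }, 0, 1, rel.tol = 1e-10)$value
  }, numeric(1))
}

random_nt <- function(n, len = 30) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

random_aa <- function(n, len = 12) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(c("C", sample(aa, len - 2, replace = TRUE), "F"), collapse = "")
  }, character(1))
}

sim_gene_ids <- function(config) {
  P <- config$n_programs
  m <- config$n_marker_genes_per_program
  markers <- as.vector(vapply(seq_len(P), function(p) {
    sprintf("SimP%dM%02d", p, seq_len(m))
  }, character(m)))
  fixed <- c("Cd8a", "Foxp3", "mt-Co1", "mt-Co2", "mt-Nd1", "mt-Nd2",
             "mt-Cytb", "Trav1", "Trbv2", "Trav7-2")
  n_bg <- config$n_genes - length(fixed) - length(markers)
  list(ids = c(fixed, markers, sprintf("Gene%04d", seq_len(n_bg))),
       marker_ids = markers, fixed = fixed,
       background_ids = sprintf("Gene%04d", seq_len(n_bg)))
}

#' Simulate a paired expression/TCR dataset with known ground truth
#'
#' Per clone: a pattern, a clone size, per-cell progressions u drawn from the
#' pattern's occupancy, program activities interpolated along the pattern
#' path, gene-level means `baseline * exp(loading %*% activity) * library
#' factor`, negative-binomial counts, tissue labels drawn from the pattern's
#' tissue split, and a clone-unique random alpha/beta V(D)J 30-mer pair.
#' Lineage markers (Cd8a, Foxp3) are set from the pattern's cd8/treg
#' identity. Fully deterministic given `seed`.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return List with `dataset` (a [tcell_dataset()]) and `ground_truth`
#'   (cells/clones tibbles, per-program and module gene sets, parameters).
#' @export
simulate_dataset <- function(config, seed) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(as.integer(seed), simulate_dataset_impl(config))
}

simulate_dataset_impl <- function(config) {
  genes <- sim_gene_ids(config)
  G <- length(genes$ids); P <- config$n_programs
  m <- config$n_marker_genes_per_program

  baseline <- stats::setNames(numeric(G), genes$ids)
  baseline[genes$marker_ids] <-
    stats::rlnorm(length(genes$marker_ids), config$marker_baseline[1],
                  config$marker_baseline[2])
  bg_like <- setdiff(genes$ids, c("Cd8a", "Foxp3", genes$marker_ids))
  baseline[bg_like] <- stats::rlnorm(length(bg_like),
                                     config$background_baseline[1],
                                     config$background_baseline[2])
  mito <- genes$ids[startsWith(genes$ids, "mt-")]
  baseline[mito] <- stats::rlnorm(length(mito), log(1), 0.3)

  # module genes: low quiescent baseline, elevated in designated cells
  module_genes <- list()
  taken <- character()
  for (mod in config$modules) {
    gset <- mod$genes
    if (is.null(gset)) {
      avail <- setdiff(genes$background_ids, taken)
      if (length(avail) < mod$n_genes) stop("not enough background genes for module",
                                            call. = FALSE)
      gset <- avail[seq_len(mod$n_genes)]
    }
    if (any(gset %in% c("Cd8a", "Foxp3"))) {
      stop("module '", mod$name, "' overlaps lineage marker genes", call. = FALSE)
    }
    taken <- c(taken, gset)
    module_genes[[mod$name]] <- gset
    # module genes keep heterogeneous baselines (set baseline_mean to force
    # one); a shared constant would pile them into a single expression bin
    # where they become each other's controls
    if (!is.null(mod$baseline_mean)) baseline[gset] <- mod$baseline_mean
  }

  loading <- matrix(0, G, P, dimnames = list(genes$ids, NULL))
  for (p in seq_len(P)) {
    loading[sprintf("SimP%dM%02d", p, seq_len(m)), p] <- config$marker_loading
  }

  n_patterns <- length(config$patterns)
  n_clones <- n_patterns * config$clones_per_pattern
  clone_pattern <- rep(seq_len(n_patterns), each = config$clones_per_pattern)
  size_range <- config$cells_per_clone
  sizes <- if (size_range[1] == size_range[2]) {
    rep(size_range[1], n_clones)
  } else {
    size_range[1] + sample.int(size_range[2] - size_range[1] + 1L, n_clones,
                               replace = TRUE) - 1L
  }

  # clone-unique TCR pairs
  repeat {
    alpha <- random_nt(n_clones); beta <- random_nt(n_clones)
    if (!anyDuplicated(paste(alpha, beta))) break
  }
  clone_ids <- clone_id_hash(alpha, beta)
  animal <- paste0("m", rep_len(1:3, n_clones))

  n_cells <- sum(sizes)
  barcodes <- sprintf("cell%06d", seq_len(n_cells))
  counts <- matrix(0L, n_cells, G, dimnames = list(barcodes, genes$ids))
  cell_rows <- split(seq_len(n_cells), rep(seq_len(n_clones), sizes))

  cells <- vector("list", n_clones)
  lm <- config$lineage_means
  for (ci in seq_len(n_clones)) {
    pat <- config$patterns[[clone_pattern[ci]]]
    rows <- cell_rows[[ci]]
    n <- length(rows)
    u <- rtrunc_mixture(n, pat$occupancy)
    act <- pattern_activity(pat, u)                       # n x P
    lib <- stats::rlnorm(n, 0, config$library_sdlog)
    log_mu <- matrix(log(baseline), n, G, byrow = TRUE) +
      act %*% t(loading)                                  # n x G
    mu <- exp(log_mu) * lib
    mu[, "Cd8a"] <- (if (pat$cd8) lm$cd8a_pos else lm$cd8a_neg) * lib
    mu[, "Foxp3"] <- (if (!pat$cd8 && pat$treg) lm$foxp3_pos else lm$foxp3_neg) * lib
    ts <- pat$tissue_split
    p_tumor <- pmin(pmax(ts[1] + ts[2] * u, 0.02), 0.98)
    tissue <- ifelse(stats::runif(n) < p_tumor, "tumor", "spleen")
    desig <- list()
    for (mod in config$modules) {
      scope <- if (is.null(mod$tissue)) rep(TRUE, n) else tissue == mod$tissue
      hit <- scope & stats::runif(n) < mod$fraction
      if (mod$log2fc != 0) {
        mu[hit, module_genes[[mod$name]]] <-
          mu[hit, module_genes[[mod$name]], drop = FALSE] * 2^mod$log2fc
      }
      desig[[paste0("is_", mod$name)]] <- hit
    }
    counts[rows, ] <- matrix(
      stats::rnbinom(n * G, mu = as.vector(mu), size = 1 / config$nb_dispersion),
      n, G)
    cells[[ci]] <- tibble::tibble(
      barcode = barcodes[rows], clone_id = clone_ids[ci],
      pattern = pat$name, u = u, tissue = tissue, lib_factor = lib,
      !!!desig)
  }
  cells <- dplyr::bind_rows(cells)

  tcr <- tibble::tibble(
    barcode = cells$barcode,
    alpha_nt = alpha[match(cells$clone_id, clone_ids)],
    beta_nt = beta[match(cells$clone_id, clone_ids)],
    alpha_cdr3_aa = random_aa(n_clones)[match(cells$clone_id, clone_ids)],
    beta_cdr3_aa = random_aa(n_clones)[match(cells$clone_id, clone_ids)],
    alpha_v = sample(sprintf("TRAV%d", 1:14), n_cells, replace = TRUE),
    alpha_j = sample(sprintf("TRAJ%d", 1:30), n_cells, replace = TRUE),
    beta_v = sample(sprintf("TRBV%d", 1:20), n_cells, replace = TRUE),
    beta_j = sample(sprintf("TRBJ%d-%d", 1:2, 1:6), n_cells, replace = TRUE),
    complete = TRUE
  )
  meta <- tibble::tibble(
    barcode = cells$barcode, tissue = cells$tissue,
    animal_id = animal[match(cells$clone_id, clone_ids)],
    fatemap_label = "positive"
  )
  dataset <- tcell_dataset(counts, genes$ids, barcodes, meta = meta, tcr = tcr)

  program_sets <- lapply(stats::setNames(seq_len(P), sprintf("program%d", seq_len(P))),
                         function(p) sprintf("SimP%dM%02d", p, seq_len(m)))
  names(program_sets)[P] <- "naive_program"

  gt <- list(
    cells = cells,
    clones = tibble::tibble(clone_id = clone_ids,
                            pattern = vapply(config$patterns, `[[`,
                                             character(1), "name")[clone_pattern],
                            alpha_nt = alpha, beta_nt = beta,
                            n_cells = sizes, animal_id = animal),
    gene_sets = c(program_sets, module_genes),
    baseline = baseline,
    params = list(n_genes = G, n_programs = P,
                  nb_dispersion = config$nb_dispersion,
                  library_sdlog = config$library_sdlog,
                  clones_per_pattern = config$clones_per_pattern,
                  cells_per_clone = config$cells_per_clone,
                  modules = lapply(config$modules, function(mod) {
                    mod$genes <- module_genes[[mod$name]]; mod
                  }))
  )
  list(dataset = dataset, ground_truth = gt)
}

#' Simulate designated scorable cell states (cycling / exhausted)
#'
#' Extends a configuration with gene modules whose genes are kept at a low
#' quiescent baseline and elevated by `log2fc` in a designated fraction of
#' cells (optionally restricted to one tissue), then simulates. Ground truth
#' records the designation per cell (`is_<name>` columns) and the module gene
#' lists, so score-based state calls can be benchmarked against truth.
#'
#' @param config a [simulation_config()].
#' @param modules list of module descriptions: `name`, `log2fc`, `fraction`,
#'   and either `genes` or `n_genes` (auto-assigned from background genes);
#'   optional `tissue` restriction and `baseline_mean` (by default module
#'   genes keep their heterogeneous background baselines so they spread
#'   across expression bins instead of forming one bin).
#' @param seed integer seed.
#' @return As [simulate_dataset()].
#' @export
simulate_scorable_states <- function(config, modules, seed) {
  config$modules <- modules
  simulate_dataset(config, seed)
}
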