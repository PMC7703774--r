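# Synthetic multi-cell-type count data with injected, labeled doublets.
#
# Each cell type owns a block of marker genes expressed at mu_marker in its
# own cells and at mu_background elsewhere; counts are negative binomial
# with a shared dispersion. Doublets are built exactly the way droplet
# doublets arise: two realized singlets are drawn and their counts summed,
# and the doublet replaces a singlet so the total cell count is unchanged.

#' Configuration for the doublet simulator
#'
#' Defaults describe a moderately sized droplet experiment: three cell
#' types of 500 cells, 1000 genes of which 50 per type are markers,
#' marker mean 5 vs background mean 0.1 (UMI-scale), negative-binomial
#' dispersion (size) 2 and a 10% doublet rate.
#'
#' @param n_types Number of cell types.
#' @param cells_per_type Cells per type (recycled to `n_types`).
#' @param n_genes Total genes; must hold all marker blocks.
#' @param markers_per_type Marker genes per type.
#' @param mu_marker NB mean of a type's markers in its own cells.
#' @param mu_background NB mean everywhere else; must be < `mu_marker`.
#' @param dispersion NB size parameter shared by all genes (smaller =
#'   more overdispersed).
#' @param doublet_rate Fraction of final barcodes that are doublets, in
#'   `[0, 1)`.
#' @param seed Integer seed; the simulation is fully reproducible.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_types = 3, cells_per_type = 500, n_genes = 1000,
                       markers_per_type = 50, mu_marker = 5,
                       mu_background = 0.1, dispersion = 2,
                       doublet_rate = 0.1, seed = 1) {
  cells_per_type <- rep_len(as.integer(cells_per_type), n_types)
  cfg <- list(n_types = as.integer(n_types),
              cells_per_type = cells_per_type,
              n_genes = as.integer(n_genes),
              markers_per_type = as.integer(markers_per_type),
              mu_marker = mu_marker, mu_background = mu_background,
              dispersion = dispersion, doublet_rate = doublet_rate,
              seed = as.integer(seed))
  stopifnot(cfg$n_types >= 1, all(cfg$cells_per_type >= 1),
            cfg$dispersion > 0, cfg$mu_background > 0)
  if (cfg$markers_per_type * cfg$n_types > cfg$n_genes) {
    stop("marker blocks do not fit into `n_genes`", call. = FALSE)
  }
  if (cfg$mu_marker <= cfg$mu_background) {
    stop("`mu_marker` must exceed `mu_background`", call. = FALSE)
  }
  if (cfg$doublet_rate < 0 || cfg$doublet_rate >= 1) {
    stop("`doublet_rate` must lie in [0, 1)", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a count matrix with labeled doublets
#'
#' Generates one singlet per requested cell (marker block elevated only in
#' the cell's own type), then replaces `round(doublet_rate * n)` randomly
#' chosen barcodes by doublets, each the count sum of two distinct
#' singlets drawn uniformly from the realized pool. Doublets of two
#' same-type parents are labeled homotypic, otherwise heterotypic.
#'
#' @param config A [sim_config()].
#' @return List with `counts` (genes x cells `dgCMatrix`), `labels`
#'   (tibble: `barcode`, `is_doublet`, `doublet_kind`, `parent_type_a`,
#'   `parent_type_b`, the parent types `NA` for singlets) and `config`.
#' @examples
#' sim <- simulate_doublets(sim_config(n_types = 2, cells_per_type = 30,
#'                                     n_genes = 80, markers_per_type = 10))
#' table(sim$labels$doublet_kind)
#' @export
simulate_doublets <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  withr::local_seed(cfg$seed)
  n_total <- sum(cfg$cells_per_type)
  cell_type <- rep.int(seq_len(cfg$n_types), cfg$cells_per_type)

  mu <- matrix(cfg$mu_background, nrow = cfg$n_genes, ncol = cfg$n_types)
  for (t in seq_len(cfg$n_types)) {
    block <- (t - 1L) * cfg$markers_per_type + seq_len(cfg$markers_per_type)
    mu[block, t] <- cfg$mu_marker
  }

  singlets <- matrix(0L, nrow = cfg$n_genes, ncol = n_total)
  for (t in seq_len(cfg$n_types)) {
    cols <- which(cell_type == t)
    singlets[, cols] <- stats::rnbinom(cfg$n_genes * length(cols),
                                       size = cfg$dispersion, mu = mu[, t])
  }

  counts <- singlets
  n_dbl <- round(cfg$doublet_rate * n_total)
  is_doublet <- logical(n_total)
  kind <- rep("not_applicable", n_total)
  parent_a <- rep(NA_integer_, n_total)
  parent_b <- rep(NA_integer_, n_total)
  if (n_dbl > 0) {
    slots <- sample.int(n_total, n_dbl)
    p1 <- sample.int(n_total, n_dbl, replace = TRUE)
    p2 <- sample.int(n_total - 1L, n_dbl, replace = TRUE)
    p2 <- p2 + (p2 >= p1)
    counts[, slots] <- singlets[, p1, drop = FALSE] +
      singlets[, p2, drop = FALSE]
    is_doublet[slots] <- TRUE
    parent_a[slots] <- cell_type[p1]
    parent_b[slots] <- cell_type[p2]
    kind[slots] <- ifelse(cell_type[p1] == cell_type[p2],
                          "homotypic", "heterotypic")
  }

  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_genes))
  barcodes <- sprintf("cell%05d", seq_len(n_total))
  labels <- tibble::tibble(
    barcode = barcodes,
    is_doublet = is_doublet,
    doublet_kind = kind,
    parent_type_a = parent_a,
    parent_type_b = parent_b
  )
  list(counts = as_count_matrix(counts, gene_ids, barcodes),
       labels = labels, config = cfg)
}

#' Write a simulated dataset to disk
#'
#' Writes the same formats the package reads: `matrix.mtx`, `genes.tsv`,
#' `barcodes.tsv` ([read_counts_mtx()]) and `labels.csv`
#' ([read_labels()]).
#'
#' @param sim Result of [simulate_doublets()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(sim, dir) {
  write_counts_mtx(sim$counts, dir)
  write_labels(sim$labels, file.path(dir, "labels.csv"))
  invisible(dir)
}
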