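#' Score doublets with one or more methods
#'
#' Orchestrates the package's scoring methods over a count matrix and
#' returns a single tidy score table: one row per barcode, one
#' `<method>_score` and `<method>_rank` column per method. `"hybrid"`
#' needs both parents and pulls in `"cxds"` and `"bcds"` automatically.
#'
#' @param X Genes x cells count matrix ([as_count_matrix()]).
#' @param methods Character vector from `"cxds"`, `"bcds"`, `"hybrid"`,
#'   `"libsize"`, `"features"`; default all five.
#' @param bin_thresh,ntop Passed to [cxds()]; `ntop` also to [bcds()].
#' @param seed Integer seed, required whenever `"bcds"` (or `"hybrid"`) is
#'   requested.
#' @param bcds_args Named list of further arguments to [bcds()]
#'   (e.g. `rounds_mode`, `cv_folds`, `n_art`).
#' @return Tibble with `barcode` plus score/rank columns; ranks are 1 =
#'   most doublet-like with ties broken by input order.
#' @examples
#' sim <- simulate_doublets(sim_config(n_types = 2, cells_per_type = 40,
#'                                     n_genes = 100, markers_per_type = 10))
#' score_doublets(sim$counts, methods = c("cxds", "libsize"))
#' @export
score_doublets <- function(X,
                           methods = c("cxds", "bcds", "hybrid",
                                       "libsize", "features"),
                           bin_thresh = 0, ntop = 500, seed = NULL,
                           bcds_args = list()) {
  known <- c("cxds", "bcds", "hybrid", "libsize", "features")
  bad <- setdiff(methods, known)
  if (length(bad)) stop("unknown method(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  X <- as_count_matrix(X)
  if ("hybrid" %in% methods) {
    methods <- union(methods, c("cxds", "bcds"))
  }
  vals <- list()
  if ("cxds" %in% methods) {
    vals$cxds <- cxds(X, bin_thresh = bin_thresh, ntop = ntop)$scores
  }
  if ("bcds" %in% methods) {
    if (is.null(seed)) {
      stop("`seed` is required for bcds scoring", call. = FALSE)
    }
    vals$bcds <- do.call(bcds, c(list(X, ntop = ntop, seed = seed),
                                 bcds_args))$scores
  }
  if ("hybrid" %in% methods) {
    vals$hybrid <- hybrid_score(vals$cxds, vals$bcds)
  }
  if ("libsize" %in% methods) {
    vals$libsize <- baseline_scores(X, "libsize")
  }
  if ("features" %in% methods) {
    vals$features <- baseline_scores(X, "features")
  }
  vals <- vals[intersect(known, names(vals))]
  out <- tibble::tibble(barcode = colnames(X))
  for (m in names(vals)) {
    out[[paste0(m, "_score")]] <- vals[[m]]
    out[[paste0(m, "_rank")]] <- doublet_rank(vals[[m]])
  }
  out
}
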