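# Benchmark-style evaluation of score tables against known labels:
# the metric panel (AUROC, corrected pAUC at 90/95/97.5% specificity,
# DG AUPRC), library-size stratification and heterotypic enrichment.

join_scores_labels <- function(scores, labels) {
  scores <- validate_score_table(scores)
  labels <- validate_labels(labels)
  if (!setequal(scores$barcode, labels$barcode) ||
      nrow(scores) != nrow(labels)) {
    stop("score and label barcodes do not match", call. = FALSE)
  }
  labels[match(scores$barcode, labels$barcode), , drop = FALSE]
}

score_methods <- function(scores) {
  sub("_score$", "", grep("_score$", names(scores), value = TRUE))
}

#' Evaluate doublet score tables against known labels
#'
#' Computes, for every `<method>_score` column, the benchmark panel:
#' AUROC, corrected partial AUC at 90%, 95% and 97.5% specificity
#' ([pauc_corrected()]) and the Davis-Goadrich AUPRC ([auprc_dg()]).
#' Barcodes must match between the two tables exactly (any order); a
#' mismatch is an error rather than a silent join.
#'
#' @param scores Score table ([score_doublets()], [read_score_table()]).
#' @param labels Label tibble with `barcode` and `is_doublet`
#'   ([read_labels()], [simulate_doublets()]).
#' @return Tibble with one row per method and columns `method`, `auroc`,
#'   `pauc90`, `pauc95`, `pauc975`, `auprc`, sorted by decreasing `auroc`
#'   (ties by `auprc`).
#' @export
evaluate_scores <- function(scores, labels) {
  lab <- join_scores_labels(scores, labels)
  y <- lab$is_doublet
  out <- purrr::map_dfr(score_methods(scores), function(m) {
    s <- scores[[paste0(m, "_score")]]
    tibble::tibble(
      method = m,
      auroc = auroc(s, y),
      pauc90 = pauc_corrected(s, y, 0.9),
      pauc95 = pauc_corrected(s, y, 0.95),
      pauc975 = pauc_corrected(s, y, 0.975),
      auprc = auprc_dg(s, y)
    )
  })
  dplyr::arrange(out, dplyr::desc(.data$auroc), dplyr::desc(.data$auprc))
}

#' Evaluation stratified by library size
#'
#' Cells are assigned to `n_bins` quantile bins of library size (first bin
#' = smallest libraries; cells sitting exactly on a boundary go to the
#' lower bin) and AUROC / AUPRC are computed within each bin. Bins in
#' which only one class is present get `NA` metrics rather than an error,
#' since small strata of a rare class routinely lack doublets.
#'
#' @inheritParams evaluate_scores
#' @param lib_sizes Numeric per-cell library sizes aligned with
#'   `scores$barcode`; typically `baseline_scores(X, "libsize")`.
#' @param n_bins Number of quantile bins (default 10).
#' @return Long tibble with `method`, `bin` (1 = smallest libraries),
#'   `n_cells`, `n_doublets`, `auroc`, `auprc`.
#' @export
stratified_eval <- function(scores, labels, lib_sizes, n_bins = 10) {
  stopifnot(n_bins >= 2)
  lab <- join_scores_labels(scores, labels)
  if (length(lib_sizes) != nrow(scores)) {
    stop("`lib_sizes` must align with the score table", call. = FALSE)
  }
  brk <- stats::quantile(lib_sizes, probs = seq(0, 1, length.out = n_bins + 1))
  brk <- unique(as.numeric(brk))
  bin_assign <- as.integer(cut(lib_sizes, breaks = brk,
                               include.lowest = TRUE, right = TRUE))
  y <- lab$is_doublet
  grid <- tidyr::expand_grid(method = score_methods(scores),
                             bin = sort(unique(bin_assign)))
  purrr::pmap_dfr(grid, function(method, bin) {
    in_bin <- which(bin_assign == bin)
    s <- scores[[paste0(method, "_score")]][in_bin]
    yy <- y[in_bin]
    defined <- any(yy) && !all(yy)
    tibble::tibble(
      method = method,
      bin = bin,
      n_cells = length(in_bin),
      n_doublets = sum(yy),
      auroc = if (defined) auroc(s, yy) else NA_real_,
      auprc = if (defined) auprc_dg(s, yy) else NA_real_
    )
  })
}

#' Enrichment of recovered doublets for heterotypic doublets
#'
#' Co-expression style methods see heterotypic doublets (parents of
#' different cell types) far more easily than homotypic ones. Among the
#' annotated doublets, this tabulates recovered (called) vs missed against
#' heterotypic vs homotypic and reports the odds ratio (with a 0.5 Haldane
#' correction whenever a table cell is zero) and the exact two-sided
#' Fisher p-value.
#'
#' @param calls Logical predicted doublet status per barcode, aligned with
#'   `labels` (e.g. [call_top_k()] on a score vector).
#' @param labels Label tibble with `barcode`, `is_doublet` and
#'   `doublet_kind`; at least one doublet of each kind is required.
#' @return One-row tibble: `odds_ratio`, `p_value`, `tp_heterotypic`,
#'   `fn_heterotypic`, `tp_homotypic`, `fn_homotypic`.
#' @export
enrichment_heterotypic <- function(calls, labels) {
  labels <- validate_labels(labels)
  if (!"doublet_kind" %in% names(labels)) {
    stop("labels lack the `doublet_kind` column", call. = FALSE)
  }
  if (length(calls) != nrow(labels)) {
    stop("calls and labels differ in length", call. = FALSE)
  }
  dbl <- labels$is_doublet
  het <- labels$doublet_kind == "heterotypic"
  hom <- labels$doublet_kind == "homotypic"
  if (!any(het) || !any(hom)) {
    stop("need at least one doublet of each kind", call. = FALSE)
  }
  calls <- as.logical(calls)
  tab <- matrix(c(
    sum(dbl & het & calls), sum(dbl & het & !calls),
    sum(dbl & hom & calls), sum(dbl & hom & !calls)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(kind = c("heterotypic", "homotypic"),
                  recovered = c("TP", "FN")))
  ct <- tab
  if (any(ct == 0)) ct <- ct + 0.5
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  p <- stats::fisher.test(tab)$p.value
  tibble::tibble(
    odds_ratio = or,
    p_value = p,
    tp_heterotypic = tab[1, 1],
    fn_heterotypic = tab[1, 2],
    tp_homotypic = tab[2, 1],
    fn_homotypic = tab[2, 2]
  )
}
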