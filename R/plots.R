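# ggplot2 views of the package's result types.

#' Score distributions by doublet status
#'
#' Density plot of each method's scores, split by true doublet status when
#' labels are supplied — the quickest visual check that a scorer separates
#' doublets from singlets.
#'
#' @param scores Score table ([score_doublets()]).
#' @param labels Optional label tibble (`barcode`, `is_doublet`).
#' @param methods Methods to show; default all present.
#' @return A ggplot object.
#' @export
plot_score_density <- function(scores, labels = NULL, methods = NULL) {
  scores <- validate_score_table(scores)
  methods <- methods %||% score_methods(scores)
  long <- tidyr::pivot_longer(
    scores[, c("barcode", paste0(methods, "_score"))],
    cols = -"barcode", names_to = "method", values_to = "score",
    names_pattern = "(.*)_score"
  )
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$score))
  if (!is.null(labels)) {
    lab <- validate_labels(labels)
    long <- dplyr::left_join(long, lab[, c("barcode", "is_doublet")],
                             by = "barcode")
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$score,
                                            fill = .data$is_doublet))
  }
  p +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::facet_wrap(~method, scales = "free") +
    ggplot2::labs(x = "doublet score", fill = "doublet")
}

#' Tile view of library-size-stratified performance
#'
#' Methods x library-size-bin heat map of a chosen metric from
#' [stratified_eval()]; undefined bins (one class only) are blank.
#'
#' @param strat Tibble from [stratified_eval()].
#' @param metric `"auroc"` or `"auprc"`.
#' @return A ggplot object.
#' @export
plot_stratified_performance <- function(strat, metric = c("auroc", "auprc")) {
  metric <- match.arg(metric)
  ggplot2::ggplot(strat, ggplot2::aes(x = factor(.data$bin), y = .data$method,
                                      fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), na.value = "grey90") +
    ggplot2::labs(x = "library-size bin (1 = smallest)", y = NULL,
                  fill = toupper(metric))
}

#' @describeIn tidy.bcds_fit CV error trajectory with the chosen number of
#'   rounds marked (CV mode) or the training-error trajectory (fixed7).
#' @param object A `bcds_fit`.
#' @method autoplot bcds_fit
#' @export
autoplot.bcds_fit <- function(object, ...) {
  if (!is.null(object$cv_log)) {
    df <- object$cv_log
    ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$error_mean)) +
      ggplot2::geom_ribbon(ggplot2::aes(
        ymin = .data$error_mean - .data$error_se,
        ymax = .data$error_mean + .data$error_se
      ), fill = "grey80") +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$n_rounds, linetype = 2) +
      ggplot2::labs(x = "boosting round", y = "CV misclassification error")
  } else {
    df <- tibble::tibble(round = seq_along(object$train_error),
                         error = object$train_error)
    ggplot2::ggplot(df, ggplot2::aes(x = .data$round, y = .data$error)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = object$n_rounds, linetype = 2) +
      ggplot2::labs(x = "boosting round", y = "training error")
  }
}

#' @describeIn tidy.cxds_fit Importance of the top gene pairs driving the
#'   annotation.
#' @param object A `cxds_fit`.
#' @param n_pairs Number of pairs shown.
#' @method autoplot cxds_fit
#' @export
autoplot.cxds_fit <- function(object, n_pairs = 10, ...) {
  tp <- top_pairs(object, n_pairs = n_pairs)
  tp$pair <- factor(paste(tp$gene_a, tp$gene_b, sep = " : "),
                    levels = rev(paste(tp$gene_a, tp$gene_b, sep = " : ")))
  ggplot2::ggplot(tp, ggplot2::aes(x = .data$importance, y = .data$pair)) +
    ggplot2::geom_col() +
    ggplot2::labs(y = NULL, x = "pair importance")
}
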