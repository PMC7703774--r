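# Scalar evaluation metrics for doublet scores against known labels.
# AUROC and the corrected partial AUC are delegated to pROC; the
# Davis-Goadrich AUPRC is computed in closed form per PR-curve segment.

check_binary_labels <- function(scores, labels, both_classes = TRUE) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  if (anyNA(scores) || anyNA(labels)) stop("missing values", call. = FALSE)
  if (both_classes && (!any(labels) || all(labels))) {
    stop("labels must contain both classes", call. = FALSE)
  }
  labels
}

proc_roc <- function(scores, labels) {
  pROC::roc(response = factor(labels, levels = c(FALSE, TRUE)),
            predictor = scores, direction = "<", quiet = TRUE)
}

#' Area under the ROC curve
#'
#' Trapezoidal AUROC (equal to the tie-corrected Mann-Whitney statistic
#' U / (n1 n0)), computed with pROC.
#'
#' @param scores Numeric doublet scores (higher = more doublet-like).
#' @param labels Logical (or 0/1) true doublet status; both classes must be
#'   present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels)
  as.numeric(pROC::auc(proc_roc(scores, labels)))
}

#' Corrected partial AUC at high specificity
#'
#' Area under the ROC curve restricted to specificity in
#' `[spec_min, 1]` (the ROC is linearly interpolated at the boundary),
#' standardized so that 1 is a perfect classifier and 0.5 is
#' non-discriminant: with `Amax = 1 - spec_min` and
#' `Amin = (1 - spec_min)^2 / 2`, the corrected value is
#' `0.5 * (1 + (A - Amin) / (Amax - Amin))`.
#'
#' @inheritParams auroc
#' @param spec_min Lower specificity bound, in (0, 1); e.g. 0.9, 0.95,
#'   0.975.
#' @return Corrected partial AUC.
#' @export
pauc_corrected <- function(scores, labels, spec_min = 0.9) {
  stopifnot(length(spec_min) == 1L, spec_min > 0, spec_min < 1)
  labels <- check_binary_labels(scores, labels)
  raw <- as.numeric(pROC::auc(proc_roc(scores, labels),
                              partial.auc = c(1, spec_min),
                              partial.auc.focus = "specificity"))
  # standardize the raw area by hand: unlike pROC's built-in correction
  # this stays defined (< 0.5) for partial curves below the chance line
  amax <- 1 - spec_min
  amin <- amax^2 / 2
  0.5 * (1 + (raw - amin) / (amax - amin))
}

#' Area under the precision-recall curve (Davis-Goadrich)
#'
#' Integrates precision over recall using the Davis-Goadrich nonlinear
#' interpolation between achievable PR points: between adjacent threshold
#' points a and b, intermediate precision at TP = x is
#' `x / (x + FP_a + s (x - TP_a))` with `s = (FP_b - FP_a)/(TP_b - TP_a)`
#' the local false-positive slope. Each segment integrates in closed form,
#' and the area is reported on the full `[0, 1]` recall scale.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`. Requires at least one positive label.
#' @export
auprc_dg <- function(scores, labels) {
  labels <- check_binary_labels(scores, labels, both_classes = FALSE)
  if (!any(labels)) stop("no positive labels", call. = FALSE)
  pts <- pr_points(scores, labels)
  P <- sum(labels)
  area <- 0
  for (i in seq_len(nrow(pts) - 1L)) {
    tp_a <- pts$tp[i]; fp_a <- pts$fp[i]
    tp_b <- pts$tp[i + 1L]; fp_b <- pts$fp[i + 1L]
    if (tp_b == tp_a) next  # vertical in FP only: no recall width
    s <- (fp_b - fp_a) / (tp_b - tp_a)
    a <- 1 + s
    cc <- fp_a - s * tp_a
    # integral of x / (a x + cc) dx over [tp_a, tp_b]; cc may be negative,
    # but a x + cc = x + fp_a + s (x - tp_a) > 0 on the segment
    if (cc == 0) {
      seg <- (tp_b - tp_a) / a
    } else {
      seg <- (tp_b - tp_a) / a -
        (cc / a^2) * (log(a * tp_b + cc) - log(a * tp_a + cc))
    }
    area <- area + seg
  }
  area / P
}

# cumulative (TP, FP) at each distinct threshold, highest scores first,
# prefixed with the (0, 0) origin
pr_points <- function(scores, labels) {
  ord <- order(-scores)
  s <- scores[ord]
  y <- labels[ord]
  starts <- which(!duplicated(s))
  ends <- c(starts[-1L] - 1L, length(s))  # last index of each score block
  tp <- cumsum(y)[ends]
  fp <- cumsum(!y)[ends]
  tibble::tibble(tp = c(0, tp), fp = c(0, fp))
}

#' Call the top k scores as doublets
#'
#' Exactly `k` cells are called: the `k` highest scores, ties broken by
#' input order. Matching `k` to the number of annotated doublets gives the
#' calling rule used for confusion-class comparisons.
#'
#' @param scores Numeric doublet scores.
#' @param k Number of calls, `0 <= k <= length(scores)`.
#' @return Logical vector of calls.
#' @export
call_top_k <- function(scores, k) {
  n <- length(scores)
  if (length(k) != 1L || is.na(k) || k < 0 || k > n) {
    stop("`k` must lie in [0, ", n, "]", call. = FALSE)
  }
  calls <- logical(n)
  ord <- order(-scores, seq_len(n))
  calls[ord[seq_len(k)]] <- TRUE
  calls
}

#' Confusion classes of doublet calls
#'
#' @param calls Logical predicted doublet status.
#' @param labels Logical true doublet status.
#' @return Character vector over `"TP"`, `"FP"`, `"FN"`, `"TN"`; the four
#'   classes partition the cells.
#' @export
confusion_classes <- function(calls, labels) {
  if (length(calls) != length(labels)) {
    stop("calls and labels differ in length", call. = FALSE)
  }
  calls <- as.logical(calls)
  labels <- as.logical(labels)
  dplyr::case_when(
    calls & labels ~ "TP",
    calls & !labels ~ "FP",
    !calls & labels ~ "FN",
    .default = "TN"
  )
}

#' Baseline doublet scores: library size and detected genes
#'
#' Doublets carry roughly twice the RNA of single cells, so total counts
#' (`"libsize"`) and the number of detected genes (`"features"`) are the
#' standard no-model baselines any doublet caller should beat.
#'
#' @param X Genes x cells count matrix.
#' @param kind `"libsize"` (column sums) or `"features"` (column-wise count
#'   of nonzero entries).
#' @return Numeric vector, one score per cell.
#' @export
baseline_scores <- function(X, kind = c("libsize", "features")) {
  kind <- match.arg(kind)
  X <- as_count_matrix(X)
  switch(kind,
    libsize = as.numeric(Matrix::colSums(X)),
    features = as.numeric(Matrix::colSums(X > 0))
  )
}
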