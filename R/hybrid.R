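# Hybrid score: min-max normalize cxds and bcds to [0, 1] and add them.

#' Min-max normalize a score vector to the unit interval
#'
#' Subtracts the minimum and divides by the resulting maximum, mapping any
#' score vector onto `[0, 1]`. A constant vector carries no ranking
#' information and maps to all zeros rather than dividing by zero.
#'
#' @param v Numeric vector, length at least 1.
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' minmax_normalize(c(2, 4, 6))
#' @export
minmax_normalize <- function(v) {
  if (!length(v)) stop("empty score vector", call. = FALSE)
  if (anyNA(v)) stop("missing scores", call. = FALSE)
  v <- v - min(v)
  mx <- max(v)
  if (mx == 0) return(rep(0, length(v)))
  v / mx
}

#' Combine cxds and bcds into the hybrid doublet score
#'
#' Both score vectors are min-max normalized to `[0, 1]` and added, so the
#' hybrid score lies in `[0, 2]` and is invariant to any positive affine
#' transform of either input. Cells flagged by both methods rise to the
#' top; disagreement between the methods is averaged out.
#'
#' @param cxds_scores,bcds_scores Numeric score vectors over the same
#'   cells, in the same order.
#' @return Numeric vector of hybrid scores.
#' @export
hybrid_score <- function(cxds_scores, bcds_scores) {
  if (length(cxds_scores) != length(bcds_scores)) {
    stop("score vectors differ in length", call. = FALSE)
  }
  minmax_normalize(cxds_scores) + minmax_normalize(bcds_scores)
}
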