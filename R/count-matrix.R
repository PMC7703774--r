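#' Validate and coerce a genes x cells count matrix
#'
#' The canonical container used throughout the package is a sparse
#' `dgCMatrix` with genes as rows and cell barcodes as columns, carrying
#' unique gene identifiers as `rownames()` and unique barcodes as
#' `colnames()`. `as_count_matrix()` accepts a base matrix or any
#' [Matrix::Matrix()] and enforces the container's invariants: all entries
#' non-negative integers, at least one gene and two cells, and no duplicated
#' identifiers.
#'
#' @param x A genes x cells matrix of non-negative integer counts
#'   (base matrix or Matrix sparse/dense matrix).
#' @param gene_ids Character vector of gene identifiers, one per row.
#'   Defaults to `rownames(x)`; generated as `"gene1"`, `"gene2"`, ... when
#'   absent.
#' @param barcodes Character vector of cell barcodes, one per column.
#'   Defaults to `colnames(x)`; generated as `"cell1"`, `"cell2"`, ... when
#'   absent.
#'
#' @return A `dgCMatrix` (genes x cells) with row and column names set.
#' @examples
#' X <- as_count_matrix(matrix(c(0, 2, 1, 0), nrow = 2))
#' dim(X)
#' @export
as_count_matrix <- function(x, gene_ids = NULL, barcodes = NULL) {
  if (is.data.frame(x)) {
    stop("`x` must be a matrix of counts, not a data frame; ",
         "use read_counts_csv() for tabular count files", call. = FALSE)
  }
  if (is.null(gene_ids)) gene_ids <- rownames(x)
  if (is.null(barcodes)) barcodes <- colnames(x)
  x <- to_dgc(x)
  m <- nrow(x)
  n <- ncol(x)
  if (m < 1L) stop("count matrix needs at least one gene", call. = FALSE)
  if (n < 2L) stop("count matrix needs at least two cells", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(m))
  if (is.null(barcodes)) barcodes <- paste0("cell", seq_len(n))
  gene_ids <- as.character(gene_ids)
  barcodes <- as.character(barcodes)
  if (length(gene_ids) != m) {
    stop("`gene_ids` has length ", length(gene_ids), " but matrix has ",
         m, " rows", call. = FALSE)
  }
  if (length(barcodes) != n) {
    stop("`barcodes` has length ", length(barcodes), " but matrix has ",
         n, " columns", call. = FALSE)
  }
  if (anyDuplicated(gene_ids)) stop("duplicated gene ids", call. = FALSE)
  if (anyDuplicated(barcodes)) stop("duplicated barcodes", call. = FALSE)
  if (length(x@x)) {
    if (anyNA(x@x)) stop("counts contain missing values", call. = FALSE)
    if (min(x@x) < 0) stop("counts must be non-negative", call. = FALSE)
    if (any(x@x != trunc(x@x))) {
      stop("counts must be integers", call. = FALSE)
    }
  }
  dimnames(x) <- list(gene_ids, barcodes)
  x
}

# coerce base/Matrix input to dgCMatrix
to_dgc <- function(x) {
  if (inherits(x, "dgCMatrix")) return(x)
  if (is.matrix(x)) {
    storage.mode(x) <- "double"
    return(methods::as(methods::as(Matrix::Matrix(x, sparse = TRUE),
                                   "generalMatrix"), "CsparseMatrix"))
  }
  if (methods::is(x, "Matrix")) {
    x <- methods::as(x, "dMatrix")
    x <- methods::as(x, "generalMatrix")
    return(methods::as(x, "CsparseMatrix"))
  }
  stop("cannot interpret `x` as a count matrix", call. = FALSE)
}

#' Rank scores from most to least doublet-like
#'
#' Rank 1 is the highest score; ties are broken by input order so that
#' repeated runs produce identical tables.
#'
#' @param scores Numeric vector of doublet scores.
#' @return Integer vector of ranks, a permutation of `seq_along(scores)`.
#' @examples
#' doublet_rank(c(1, 3, 3, 0))
#' @export
doublet_rank <- function(scores) {
  stopifnot(is.numeric(scores), length(scores) >= 1L, !anyNA(scores))
  ord <- order(-scores, seq_along(scores))
  rk <- integer(length(scores))
  rk[ord] <- seq_along(scores)
  rk
}
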