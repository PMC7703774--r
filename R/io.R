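#' Read a 10x-style MatrixMarket count matrix
#'
#' Reads a sparse count matrix stored in MatrixMarket coordinate format
#' together with its gene and barcode lists (one entry per line, TSV;
#' multi-column files such as 10x `genes.tsv` with id + symbol are accepted
#' and the first column is used as the identifier).
#'
#' The stored orientation is inferred by matching the matrix header
#' dimensions against the lengths of the two id files, so both genes x cells
#' and cells x genes triplet files load into the same canonical genes x
#' cells container. A square matrix is ambiguous and is taken as genes x
#' cells with a warning.
#'
#' @param matrix_path Path to the `.mtx` coordinate file.
#' @param genes_path Path to the gene list (TSV, first column = gene id).
#' @param barcodes_path Path to the barcode list (TSV, first column =
#'   barcode).
#'
#' @return A genes x cells `dgCMatrix`, see [as_count_matrix()].
#' @seealso [write_counts_mtx()], [read_counts_csv()]
#' @export
read_counts_mtx <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  x <- Matrix::readMM(matrix_path)
  genes <- read_id_column(genes_path)
  barcodes <- read_id_column(barcodes_path)
  m <- length(genes)
  n <- length(barcodes)
  if (nrow(x) == m && ncol(x) == n) {
    if (m == n) {
      warning("square matrix: orientation ambiguous, assuming genes x cells",
              call. = FALSE)
    }
  } else if (nrow(x) == n && ncol(x) == m) {
    x <- Matrix::t(x)
  } else {
    stop("matrix is ", nrow(x), " x ", ncol(x), " but gene/barcode files ",
         "have ", m, " and ", n, " entries", call. = FALSE)
  }
  as_count_matrix(x, gene_ids = genes, barcodes = barcodes)
}

read_id_column <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "")
  tab[[1L]]
}

#' Write a count matrix as MatrixMarket + gene/barcode TSVs
#'
#' @param X Genes x cells count matrix ([as_count_matrix()]).
#' @param dir Output directory, created if needed. Files written are
#'   `matrix.mtx`, `genes.tsv`, `barcodes.tsv`.
#' @return `dir`, invisibly.
#' @export
write_counts_mtx <- function(X, dir) {
  X <- as_count_matrix(X)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(X, file.path(dir, "matrix.mtx"))
  writeLines(rownames(X), file.path(dir, "genes.tsv"))
  writeLines(colnames(X), file.path(dir, "barcodes.tsv"))
  invisible(dir)
}

#' Read a dense CSV count matrix
#'
#' Expects gene identifiers in the first column, barcodes as the header row
#' and non-negative integer counts in the body.
#'
#' @param path CSV file path.
#' @return A genes x cells `dgCMatrix`, see [as_count_matrix()].
#' @export
read_counts_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, col_types = readr::cols(
    readr::col_character(), .default = readr::col_double()
  ), progress = FALSE, name_repair = "minimal")
  if (nrow(readr::problems(tab)) > 0) {
    stop("malformed count CSV: ", path, call. = FALSE)
  }
  counts <- as.matrix(tab[, -1, drop = FALSE])
  if (anyNA(counts)) stop("non-numeric or missing counts in ", path,
                          call. = FALSE)
  as_count_matrix(counts, gene_ids = tab[[1L]],
                  barcodes = colnames(tab)[-1L])
}

#' Write a dense CSV count matrix
#'
#' @param X Genes x cells count matrix.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_counts_csv <- function(X, path) {
  X <- as_count_matrix(X)
  tab <- tibble::as_tibble(as.matrix(X), .name_repair = "minimal")
  tab <- dplyr::bind_cols(tibble::tibble(gene_id = rownames(X)), tab)
  readr::write_csv(tab, path, progress = FALSE)
  invisible(path)
}

#' Read / write per-cell doublet labels
#'
#' The label CSV has columns `barcode`, `is_doublet` (logical or 0/1) and
#' optionally `doublet_kind` (`"heterotypic"`, `"homotypic"` or
#' `"not_applicable"`; singlets must be `not_applicable`).
#'
#' @param path CSV path.
#' @return A tibble with columns `barcode`, `is_doublet` and (if present)
#'   `doublet_kind`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, col_types = readr::cols(
    barcode = readr::col_character(),
    is_doublet = readr::col_logical(),
    .default = readr::col_character()
  ), progress = FALSE)
  validate_labels(tab)
}

#' @rdname read_labels
#' @param labels Label tibble as returned by [read_labels()] or
#'   [simulate_doublets()].
#' @export
write_labels <- function(labels, path) {
  labels <- validate_labels(labels)
  readr::write_csv(labels, path, progress = FALSE)
  invisible(path)
}

validate_labels <- function(labels) {
  labels <- tibble::as_tibble(labels)
  if (!all(c("barcode", "is_doublet") %in% names(labels))) {
    stop("labels need `barcode` and `is_doublet` columns", call. = FALSE)
  }
  if (anyDuplicated(labels$barcode)) {
    stop("duplicated barcodes in labels", call. = FALSE)
  }
  labels$is_doublet <- as.logical(labels$is_doublet)
  if (anyNA(labels$is_doublet)) stop("missing is_doublet values",
                                     call. = FALSE)
  if ("doublet_kind" %in% names(labels)) {
    ok <- labels$doublet_kind %in% c("heterotypic", "homotypic",
                                     "not_applicable")
    if (!all(ok)) stop("invalid doublet_kind values", call. = FALSE)
    if (any(!labels$is_doublet &
            labels$doublet_kind != "not_applicable")) {
      stop("singlets must have doublet_kind = not_applicable", call. = FALSE)
    }
  }
  labels
}

#' Read / write a doublet score table
#'
#' A score table is a tibble with a `barcode` column plus one
#' `<method>_score` and one `<method>_rank` column per scoring method
#' (`cxds`, `bcds`, `hybrid`, `libsize`, `features`). Ranks run from 1
#' (most doublet-like) to n and break ties by input order. Scores
#' round-trip through CSV at full double precision.
#'
#' @param scores Score table tibble, e.g. from [score_doublets()].
#' @param path CSV path.
#' @return `read_score_table()` returns the tibble; `write_score_table()`
#'   returns `path` invisibly.
#' @export
write_score_table <- function(scores, path) {
  scores <- validate_score_table(scores)
  readr::write_csv(scores, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- readr::read_csv(path, col_types = readr::cols(
    barcode = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  validate_score_table(tab)
}

validate_score_table <- function(scores) {
  scores <- tibble::as_tibble(scores)
  if (!"barcode" %in% names(scores)) {
    stop("score table needs a `barcode` column", call. = FALSE)
  }
  score_cols <- grep("_score$", names(scores), value = TRUE)
  if (!length(score_cols)) {
    stop("score table has no `*_score` columns", call. = FALSE)
  }
  n <- nrow(scores)
  for (sc in score_cols) {
    rc <- sub("_score$", "_rank", sc)
    if (!rc %in% names(scores)) {
      scores[[rc]] <- doublet_rank(scores[[sc]])
    } else {
      scores[[rc]] <- as.integer(scores[[rc]])
      if (!setequal(scores[[rc]], seq_len(n))) {
        stop("`", rc, "` is not a permutation of 1..n", call. = FALSE)
      }
    }
  }
  scores
}
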