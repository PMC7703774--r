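# Co-expression based doublet scoring.
#
# Heterotypic doublets co-express marker genes of two cell types that never
# co-occur in genuine single cells. Working on a binarized
# (absence/presence) version B of the count matrix, every gene pair gets a
# score: the negative log upper-tail p-value of the number of cells
# expressing exactly one of the two genes, under a binomial null that
# assumes the genes independent. Pairs co-expressed less often than their
# marginal frequencies predict score high. A cell's doublet score sums the
# pair scores over all gene pairs it co-expresses: cxds(i) = diag(B'SB)_i.

# -log p-values below this are capped so downstream sums stay finite
.score_cap <- 745

#' Binarize a count matrix
#'
#' Entry (i, j) of the result is 1 exactly when gene i has strictly more
#' than `bin_thresh` counts in cell j. The default threshold 0 marks any
#' detected gene as present.
#'
#' @param X Genes x cells count matrix ([as_count_matrix()]).
#' @param bin_thresh Non-negative integer count threshold.
#' @return Sparse 0/1 `dgCMatrix` of the same dimension as `X`.
#' @examples
#' binarize_counts(matrix(c(0, 1, 2, 0), 2), bin_thresh = 1)
#' @export
binarize_counts <- function(X, bin_thresh = 0) {
  X <- as_count_matrix(X)
  if (length(bin_thresh) != 1L || is.na(bin_thresh) || bin_thresh < 0) {
    stop("`bin_thresh` must be a single non-negative integer", call. = FALSE)
  }
  to_dgc((X > bin_thresh) * 1)
}

#' Select genes by binomial variance of their detection frequency
#'
#' Ranks genes of a binarized matrix by n * p * (1 - p), where p is the
#' fraction of cells expressing the gene, and keeps the `ntop` most
#' variable. Genes detected in no cell or in every cell carry no pairing
#' information (variance 0) and are never selected; ties go to the
#' smaller row index.
#'
#' @param B Binarized genes x cells matrix from [binarize_counts()].
#' @param ntop Maximum number of genes to keep (default 500).
#' @return Integer vector of selected row indices, length
#'   `min(ntop, number of positive-variance genes)`.
#' @export
select_genes_binomial_variance <- function(B, ntop = 500) {
  stopifnot(ntop >= 2)
  n <- ncol(B)
  p <- Matrix::rowSums(B) / n
  v <- n * p * (1 - p)
  keep <- which(unname(v) > 0)
  if (length(keep) < 2L) {
    stop("fewer than two genes with positive binomial variance; ",
         "no gene pairs can be scored", call. = FALSE)
  }
  unname(keep[order(-v[keep], keep)][seq_len(min(ntop, length(keep)))])
}

#' Negative log upper-tail binomial p-value
#'
#' Computes -log P(K >= k) for K ~ Binomial(n, q) with the inclusive upper
#' tail, in log space. `k = 0` returns exactly 0 (P(K >= 0) = 1). Values
#' whose tail probability underflows the double range are capped at a large
#' finite constant (745) so that sums over pairs stay finite.
#'
#' Arguments are recycled to a common length.
#'
#' @param k Observed count(s), `0 <= k <= n`.
#' @param n Number of trials.
#' @param q Success probability in `[0, 1]`.
#' @return Numeric vector of non-negative scores (natural log scale).
#' @examples
#' binom_neg_log_upper_tail(4, 4, 0.5)  # -log(1/16)
#' @export
binom_neg_log_upper_tail <- function(k, n, q) {
  if (anyNA(k) || anyNA(n) || anyNA(q)) stop("missing inputs", call. = FALSE)
  if (any(q < 0 | q > 1)) stop("`q` must lie in [0, 1]", call. = FALSE)
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  if (any(k != trunc(k)) || any(n != trunc(n))) {
    stop("`k` and `n` must be integers", call. = FALSE)
  }
  s <- -stats::pbinom(k - 1, n, q, lower.tail = FALSE, log.p = TRUE)
  pmin(s, .score_cap)
}

#' Score all gene pairs of a binarized matrix
#'
#' For genes i and j with detection frequencies p_i and p_j, the number of
#' cells expressing exactly one of the two is, under independence,
#' Binomial(n, p_i (1 - p_j) + p_j (1 - p_i)). The pair score is the
#' negative log inclusive upper-tail p-value of the observed exactly-one
#' count: it is high when the genes co-express more often than chance
#' predicts (so the exactly-one count falls short), which is the signature
#' of marker genes mixed together in doublets.
#'
#' @param B Binarized (0/1) selected-genes x cells matrix with at least two
#'   rows and two columns.
#' @return An object of class `gene_pair_scores`: a list with the symmetric
#'   score matrix `S` (zero diagonal), the integer matrix
#'   `exactly_one_counts`, the marginal frequencies `p` and `n_cells`.
#' @export
gene_pair_scores <- function(B) {
  if (nrow(B) < 2L) stop("need at least two genes", call. = FALSE)
  if (ncol(B) < 2L) stop("need at least two cells", call. = FALSE)
  n <- ncol(B)
  ni <- Matrix::rowSums(B)
  co <- as.matrix(Matrix::tcrossprod(B))
  ex1 <- outer(ni, ni, "+") - 2 * co
  p <- ni / n
  q <- outer(p, 1 - p) + outer(1 - p, p)
  S <- matrix(binom_neg_log_upper_tail(as.vector(ex1), n, as.vector(q)),
              nrow = nrow(B), dimnames = dimnames(ex1))
  n_capped <- sum(S[upper.tri(S)] >= .score_cap)
  if (n_capped > 0) {
    message(n_capped, " gene pair(s) hit the underflow score cap")
  }
  structure(
    list(S = S, exactly_one_counts = ex1, p = p, n_cells = n),
    class = "gene_pair_scores"
  )
}

#' Per-cell co-expression doublet scores from a binary matrix
#'
#' Evaluates diag(B'SB): for each cell, the sum of pair scores over all
#' ordered pairs of genes the cell expresses (each unordered pair counts
#' twice; self-pairs contribute zero because the diagonal of S is zero).
#' A cell expressing at most one selected gene scores exactly 0.
#'
#' @param B Binarized selected-genes x cells matrix.
#' @param S Symmetric gene-pair score matrix matching `nrow(B)`.
#' @return Numeric vector of non-negative scores, one per cell.
#' @export
cxds_cell_scores <- function(B, S) {
  if (!is.matrix(S) || nrow(S) != ncol(S) || nrow(S) != nrow(B)) {
    stop("`S` must be square and match the genes in `B`", call. = FALSE)
  }
  as.numeric(Matrix::colSums(B * (S %*% B)))
}

#' Co-expression based doublet scoring (cxds)
#'
#' Runs the full cxds pipeline on a count matrix: binarize at `bin_thresh`,
#' keep the `ntop` genes with the largest binomial variance, score all gene
#' pairs ([gene_pair_scores()]) and sum each cell's co-expressed pair
#' scores ([cxds_cell_scores()]). Cells are ranked from most to least
#' doublet-like; the scoring is fully deterministic.
#'
#' @param X Genes x cells count matrix ([as_count_matrix()]).
#' @param bin_thresh Count threshold for presence, default 0.
#' @param ntop Number of variable genes retained, default 500.
#' @return An object of class `cxds_fit` with elements `scores` (per cell),
#'   `barcodes`, `selected` (row indices of retained genes), `gene_ids`
#'   (their identifiers), `B` (binarized selected matrix), `pair_scores`
#'   (a [gene_pair_scores()] object) and the parameters used. Use
#'   [tidy()][generics::tidy] for a per-barcode tibble, [top_pairs()] for
#'   the gene pairs driving the annotation.
#' @examples
#' sim <- simulate_doublets(sim_config(n_types = 2, cells_per_type = 50,
#'                                     n_genes = 120, markers_per_type = 15))
#' fit <- cxds(sim$counts)
#' head(tidy(fit))
#' @export
cxds <- function(X, bin_thresh = 0, ntop = 500) {
  X <- as_count_matrix(X)
  Bfull <- binarize_counts(X, bin_thresh)
  sel <- select_genes_binomial_variance(Bfull, ntop)
  B <- Bfull[sel, , drop = FALSE]
  ps <- gene_pair_scores(B)
  scores <- cxds_cell_scores(B, ps$S)
  structure(
    list(scores = scores, barcodes = colnames(X), selected = sel,
         gene_ids = rownames(X)[sel], B = B, pair_scores = ps,
         bin_thresh = bin_thresh, ntop = ntop),
    class = "cxds_fit"
  )
}

#' @export
print.cxds_fit <- function(x, ...) {
  cat("cxds doublet scoring\n")
  cat("  cells:", length(x$scores), " selected genes:", length(x$selected),
      "\n")
  cat("  bin_thresh:", x$bin_thresh, " ntop:", x$ntop, "\n")
  invisible(x)
}

#' cxds scores as a tibble
#'
#' @param x A `cxds_fit` object.
#' @param ... Unused.
#' @return Tibble with `barcode`, `cxds_score` and `cxds_rank` (1 = most
#'   doublet-like, ties by input order).
#' @method tidy cxds_fit
#' @export
tidy.cxds_fit <- function(x, ...) {
  tibble::tibble(
    barcode = x$barcodes,
    cxds_score = x$scores,
    cxds_rank = doublet_rank(x$scores)
  )
}

#' @rdname tidy.cxds_fit
#' @method glance cxds_fit
#' @export
glance.cxds_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$scores),
    n_genes_selected = length(x$selected),
    bin_thresh = x$bin_thresh,
    ntop = x$ntop,
    mean_score = mean(x$scores),
    max_score = max(x$scores)
  )
}

#' Gene-pair importance decomposition of cxds scores
#'
#' Because a cell's score is a plain sum of pair scores, the aggregate
#' contribution of the pair (k, j) to the annotation is
#' imp(k, j) = sum_i cxds(i) B_ki B_ji S_kj = (B D B') * S, with D the
#' diagonal matrix of cell scores and `*` the elementwise product. The sum
#' over cells may be restricted to a subset (a cluster, or a single cell
#' for per-cell attribution).
#'
#' The total importance over all ordered pairs equals sum_i cxds(i)^2.
#'
#' @param fit A `cxds_fit` object.
#' @param cells Optional integer vector of cell indices to restrict the sum
#'   to (default: all cells).
#' @return Symmetric non-negative importance matrix over the selected
#'   genes, with gene identifiers as dimnames.
#' @export
pair_importance <- function(fit, cells = NULL) {
  stopifnot(inherits(fit, "cxds_fit"))
  w <- fit$scores
  if (!is.null(cells)) {
    cells <- as.integer(cells)
    if (any(cells < 1L | cells > length(w)) || anyNA(cells)) {
      stop("`cells` indices out of range", call. = FALSE)
    }
    keep <- logical(length(w))
    keep[cells] <- TRUE
    w[!keep] <- 0
  }
  BD <- fit$B %*% Matrix::Diagonal(x = w)
  imp <- as.matrix(Matrix::tcrossprod(BD, fit$B)) * fit$pair_scores$S
  dimnames(imp) <- list(fit$gene_ids, fit$gene_ids)
  imp
}

#' Top gene pairs driving doublet annotation
#'
#' Ranks unordered gene pairs by their [pair_importance()], the natural way
#' to inspect which marker-gene combinations the co-expression score is
#' picking up in a dataset.
#'
#' @inheritParams pair_importance
#' @param n_pairs Number of pairs to return (default 10; truncated to the
#'   number of available pairs).
#' @return Tibble with `gene_a`, `gene_b` and `importance`, sorted by
#'   decreasing importance, ties by index order.
#' @export
top_pairs <- function(fit, n_pairs = 10, cells = NULL) {
  stopifnot(n_pairs >= 1)
  imp <- pair_importance(fit, cells = cells)
  ut <- which(upper.tri(imp), arr.ind = TRUE)
  ord <- order(-imp[ut], ut[, 1L], ut[, 2L])
  ord <- ord[seq_len(min(n_pairs, length(ord)))]
  tibble::tibble(
    gene_a = rownames(imp)[ut[ord, 1L]],
    gene_b = colnames(imp)[ut[ord, 2L]],
    importance = imp[ut[ord, , drop = FALSE]]
  )
}

#' One-call cxds score table
#'
#' Convenience wrapper returning [cxds()] results directly as a tibble.
#'
#' @inheritParams cxds
#' @return Tibble with `barcode`, `cxds_score`, `cxds_rank`.
#' @export
cxds_score <- function(X, bin_thresh = 0, ntop = 500) {
  tidy.cxds_fit(cxds(X, bin_thresh = bin_thresh, ntop = ntop))
}
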