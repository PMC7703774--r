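# Binary-classification based doublet scoring: build artificial doublets by
# summing random pairs of cells, then train gradient boosted trees to tell
# artificial doublets from real barcodes. Barcodes the classifier cannot
# separate from artificial doublets get high doublet scores.

#' Select genes by variance of centered log counts
#'
#' Per gene, computes the variance across cells of ln(1 + count) after
#' subtracting the gene mean (centering leaves the variance unchanged but
#' mirrors the feature construction used for classification). The `ntop`
#' most variable genes are kept, ties by smaller row index. Selection uses
#' the original cells only, before any doublet simulation.
#'
#' @param X Genes x cells count matrix.
#' @param ntop Number of genes to keep (default 500).
#' @return Integer vector of selected row indices.
#' @export
select_genes_logvar <- function(X, ntop = 500) {
  stopifnot(ntop >= 2)
  X <- as_count_matrix(X)
  lf <- log1p(X)
  n <- ncol(X)
  mu <- Matrix::rowMeans(lf)
  v <- (Matrix::rowSums(lf^2) - n * mu^2) / (n - 1)
  keep <- which(unname(v) > 0)
  if (!length(keep)) {
    stop("all genes are constant across cells", call. = FALSE)
  }
  unname(keep[order(-v[keep], keep)][seq_len(min(ntop, length(keep)))])
}

#' Simulate artificial doublets by summing random cell pairs
#'
#' Each artificial doublet is the elementwise sum of the counts of two
#' distinct cells drawn uniformly from the input; pairs are drawn
#' independently, so a cell may parent several doublets.
#'
#' @param X Genes x cells count matrix (typically already restricted to
#'   selected genes).
#' @param n_art Number of artificial doublets (default: one per input cell,
#'   giving balanced classes).
#' @param seed Optional integer seed; when supplied the RNG state is set
#'   locally and restored afterwards. When `NULL` the current RNG stream is
#'   used (as inside [bcds()]).
#' @return List with `counts` (genes x (n + n_art) matrix: original cells
#'   then artificial doublets), `labels` (0 = original, 1 = artificial) and
#'   `parent_pairs` (n_art x 2 integer matrix of parent cell indices).
#' @export
make_artificial_doublets <- function(X, n_art = ncol(X), seed = NULL) {
  X <- as_count_matrix(X)
  n <- ncol(X)
  if (n < 2L) stop("need at least two cells to form doublets", call. = FALSE)
  if (n_art < 1L) stop("`n_art` must be at least 1", call. = FALSE)
  if (!is.null(seed)) withr::local_seed(seed)
  i1 <- sample.int(n, n_art, replace = TRUE)
  i2 <- sample.int(n - 1L, n_art, replace = TRUE)
  i2 <- i2 + (i2 >= i1)
  art <- X[, i1, drop = FALSE] + X[, i2, drop = FALSE]
  colnames(art) <- paste0("artdbl", seq_len(n_art))
  list(
    counts = cbind(X, art),
    labels = c(rep(0L, n), rep(1L, n_art)),
    parent_pairs = cbind(i1, i2, deparse.level = 0)
  )
}

#' Gene-wise centered log counts
#'
#' Applies ln(1 + count) entrywise, then subtracts each gene's mean
#' computed over all supplied cells (original cells and artificial doublets
#' together). Constant genes map to all-zero rows.
#'
#' @param counts Genes x cells matrix of non-negative counts.
#' @return Dense base matrix of centered log counts, same dimensions.
#' @export
normalize_logcounts <- function(counts) {
  if (length(counts) && min(counts) < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  lf <- as.matrix(log1p(counts))
  lf - rowMeans(lf)
}

#' Pick the number of boosting rounds by the one-standard-error rule
#'
#' Given per-round cross-validated misclassification error means and their
#' standard errors, finds the minimizing round r* (earliest on ties) and
#' returns the smallest round whose mean error is within one standard
#' error (taken at r*) of the minimum — the simplest model statistically
#' indistinguishable from the best one.
#'
#' @param cv_error_means,cv_error_ses Equal-length numeric vectors of mean
#'   CV misclassification errors and their standard errors, by round.
#' @return Integer round number.
#' @examples
#' choose_rounds_one_se(c(0.30, 0.20, 0.18, 0.19), rep(0.02, 4))  # 2
#' @export
choose_rounds_one_se <- function(cv_error_means, cv_error_ses) {
  if (!length(cv_error_means)) stop("empty CV trajectory", call. = FALSE)
  if (length(cv_error_means) != length(cv_error_ses)) {
    stop("means and standard errors differ in length", call. = FALSE)
  }
  r_star <- which.min(cv_error_means)
  thr <- cv_error_means[r_star] + cv_error_ses[r_star]
  # small slack so means sitting exactly on the threshold are not excluded
  # by floating-point round-off
  min(which(cv_error_means <= thr + 1e-10))
}

# two consecutive rounds without a decrease in error?
stalled <- function(errs, r) {
  r >= 3L && errs[r] >= errs[r - 1L] && errs[r - 1L] >= errs[r - 2L]
}

# stratified fold assignment: each class spread evenly over folds
assign_folds <- function(labels, k) {
  folds <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# round-by-round k-fold CV of boosted trees, tracking the mean
# misclassification error and its standard error across folds; stops once
# the mean error has failed to decrease for two consecutive rounds
cv_error_trajectory <- function(features, labels, folds, params, max_rounds) {
  k <- max(folds)
  dtrain <- vector("list", k)
  dtest <- vector("list", k)
  ytest <- vector("list", k)
  models <- vector("list", k)
  for (f in seq_len(k)) {
    te <- folds == f
    dtrain[[f]] <- xgboost::xgb.DMatrix(features[!te, , drop = FALSE],
                                        label = labels[!te], nthread = 1)
    dtest[[f]] <- xgboost::xgb.DMatrix(features[te, , drop = FALSE],
                                       nthread = 1)
    ytest[[f]] <- labels[te]
  }
  means <- numeric(0)
  ses <- numeric(0)
  for (r in seq_len(max_rounds)) {
    errs <- vapply(seq_len(k), function(f) {
      models[[f]] <<- xgboost::xgb.train(params, dtrain[[f]], nrounds = 1,
                                         verbose = 0,
                                         xgb_model = models[[f]])
      pred <- predict(models[[f]], dtest[[f]])
      mean((pred > 0.5) != ytest[[f]])
    }, numeric(1))
    means[r] <- mean(errs)
    ses[r] <- stats::sd(errs) / sqrt(k)
    if (stalled(means, r)) break
  }
  list(error_mean = means, error_se = ses)
}

# training-error trajectory on the full data, same stopping rule; returns
# the best round seen (used by the fixed-7-rounds heuristic)
train_error_rounds <- function(dall, labels, params, max_rounds) {
  errs <- numeric(0)
  model <- NULL
  for (r in seq_len(max_rounds)) {
    model <- xgboost::xgb.train(params, dall, nrounds = 1, verbose = 0,
                                xgb_model = model)
    pred <- predict(model, dall)
    errs[r] <- mean((pred > 0.5) != labels)
    if (stalled(errs, r)) break
  }
  list(n_rounds = which.min(errs), train_error = errs)
}

#' Binary-classification based doublet scoring (bcds)
#'
#' Full bcds pipeline: select the `ntop` genes with the largest variance of
#' centered log counts ([select_genes_logvar()]), simulate `n_art`
#' artificial doublets by summing random cell pairs
#' ([make_artificial_doublets()]), build gene-wise centered log-count
#' features over the augmented data ([normalize_logcounts()]), establish
#' the number of boosting rounds, train gradient boosted trees (xgboost,
#' library defaults) on the complete augmented set and report each original
#' barcode's predicted probability of belonging to the artificial-doublet
#' class as its doublet score.
#'
#' Two round-selection heuristics are available. `"cv_one_se"` (default)
#' runs `cv_folds`-fold cross-validation on the augmented data, tracking
#' the per-round mean misclassification error and its standard error
#' across folds, stops once the mean error has failed to decrease for two
#' consecutive rounds, and applies the one-standard-error rule
#' ([choose_rounds_one_se()]). `"fixed7"` trains for (at most) seven
#' rounds, with the same two-consecutive-rounds stopping check applied to
#' the training error; it trades a little accuracy for speed.
#'
#' @param X Genes x cells count matrix.
#' @param ntop Number of variable genes (default 500).
#' @param n_art Number of artificial doublets; default `ncol(X)` for 1:1
#'   balanced classes.
#' @param rounds_mode `"cv_one_se"` or `"fixed7"`.
#' @param cv_folds Cross-validation folds (default 5).
#' @param max_rounds Upper bound on boosting rounds under CV (default 500).
#' @param seed Integer seed; required, the pipeline is stochastic (doublet
#'   parents, fold assignment). Results are reproducible given the seed.
#' @param params Named list of xgboost parameter overrides; defaults are
#'   the library defaults with a binary logistic objective,
#'   misclassification-error metric and a single thread.
#' @return Object of class `bcds_fit` with `scores` (original cells only,
#'   in `[0, 1]`), `augmented_scores` (original cells then artificial
#'   doublets), `barcodes`, `n_rounds`, `rounds_mode`, `cv_log` (tibble
#'   of the CV error trajectory, `"cv_one_se"` only), `train_error`
#'   (`"fixed7"` only), `selected`, `parent_pairs`, `params`, `seed`.
#'   [tidy()][generics::tidy] gives the per-barcode score table,
#'   [glance()][generics::glance] a one-row run summary,
#'   [autoplot()][ggplot2::autoplot] the CV error trajectory.
#' @export
bcds <- function(X, ntop = 500, n_art = NULL,
                 rounds_mode = c("cv_one_se", "fixed7"),
                 cv_folds = 5, max_rounds = 500, seed, params = list()) {
  rounds_mode <- match.arg(rounds_mode)
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is required: bcds samples doublet parents and CV folds",
         call. = FALSE)
  }
  stopifnot(cv_folds >= 2, max_rounds >= 1)
  X <- as_count_matrix(X)
  n <- ncol(X)
  if (is.null(n_art)) n_art <- n
  if (n_art < 1L) stop("`n_art` must be at least 1", call. = FALSE)
  if (rounds_mode == "cv_one_se" && n < cv_folds) {
    stop("need at least `cv_folds` cells for cross-validation",
         call. = FALSE)
  }
  withr::local_seed(seed)

  sel <- select_genes_logvar(X, ntop)
  aug <- make_artificial_doublets(X[sel, , drop = FALSE], n_art = n_art)
  features <- t(normalize_logcounts(aug$counts))
  labels <- aug$labels

  xparams <- utils::modifyList(
    list(objective = "binary:logistic", eval_metric = "error", nthread = 1),
    params
  )
  xparams <- do.call(xgboost::xgb.params, xparams)
  dall <- xgboost::xgb.DMatrix(features, label = labels, nthread = 1)

  cv_log <- NULL
  train_error <- NULL
  if (rounds_mode == "cv_one_se") {
    folds <- assign_folds(labels, cv_folds)
    traj <- cv_error_trajectory(features, labels, folds, xparams, max_rounds)
    n_rounds <- choose_rounds_one_se(traj$error_mean, traj$error_se)
    cv_log <- tibble::tibble(
      round = seq_along(traj$error_mean),
      error_mean = traj$error_mean,
      error_se = traj$error_se
    )
  } else {
    fr <- train_error_rounds(dall, labels, xparams, max_rounds = 7L)
    n_rounds <- fr$n_rounds
    train_error <- fr$train_error
  }

  model <- xgboost::xgb.train(xparams, dall, nrounds = n_rounds, verbose = 0)
  augmented_scores <- predict(model, dall)
  scores <- augmented_scores[seq_len(n)]

  structure(
    list(scores = scores, augmented_scores = augmented_scores,
         barcodes = colnames(X), n_rounds = n_rounds,
         rounds_mode = rounds_mode, cv_log = cv_log,
         train_error = train_error, selected = sel,
         gene_ids = rownames(X)[sel], parent_pairs = aug$parent_pairs,
         params = xparams, cv_folds = cv_folds, n_art = n_art, seed = seed),
    class = "bcds_fit"
  )
}

#' @export
print.bcds_fit <- function(x, ...) {
  cat("bcds doublet scoring\n")
  cat("  cells:", length(x$scores), " artificial doublets:", x$n_art, "\n")
  cat("  rounds:", x$n_rounds, sprintf("(%s)", x$rounds_mode),
      " seed:", x$seed, "\n")
  invisible(x)
}

#' bcds scores as a tibble
#'
#' @param x A `bcds_fit` object.
#' @param ... Unused.
#' @return Tibble with `barcode`, `bcds_score` and `bcds_rank`.
#' @method tidy bcds_fit
#' @export
tidy.bcds_fit <- function(x, ...) {
  tibble::tibble(
    barcode = x$barcodes,
    bcds_score = x$scores,
    bcds_rank = doublet_rank(x$scores)
  )
}

#' @rdname tidy.bcds_fit
#' @method glance bcds_fit
#' @export
glance.bcds_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$scores),
    n_art = x$n_art,
    n_genes_selected = length(x$selected),
    rounds_mode = x$rounds_mode,
    n_rounds = x$n_rounds,
    min_cv_error = if (is.null(x$cv_log)) NA_real_ else
      min(x$cv_log$error_mean),
    seed = x$seed
  )
}

#' Machine-readable run log for a bcds fit
#'
#' @param fit A `bcds_fit` object.
#' @return A plain list (seed, rounds, CV trajectory, parameters, versions)
#'   suitable for JSON serialization.
#' @export
bcds_run_log <- function(fit) {
  stopifnot(inherits(fit, "bcds_fit"))
  list(
    seed = fit$seed,
    rounds_mode = fit$rounds_mode,
    n_rounds = fit$n_rounds,
    cv_error_mean = fit$cv_log$error_mean,
    cv_error_se = fit$cv_log$error_se,
    train_error = fit$train_error,
    n_art = fit$n_art,
    cv_folds = fit$cv_folds,
    params = fit$params[!vapply(fit$params, is.null, logical(1))],
    xgboost_version = as.character(utils::packageVersion("xgboost")),
    package_version = as.character(utils::packageVersion("doubletscore"))
  )
}

#' One-call bcds score table
#'
#' @inheritParams bcds
#' @param ... Passed to [bcds()].
#' @return Tibble with `barcode`, `bcds_score`, `bcds_rank`.
#' @export
bcds_score <- function(X, seed, ...) {
  tidy.bcds_fit(bcds(X, seed = seed, ...))
}
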