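test_that("binarization is strict and monotone in the threshold", {
  X <- matrix(c(0, 2, 1, 0), nrow = 2)
  expect_equal(unname(as.matrix(binarize_counts(X, 0))),
               matrix(c(0, 1, 1, 0), 2))
  expect_equal(unname(as.matrix(binarize_counts(X, 1))),
               matrix(c(0, 1, 0, 0), 2))
  expect_error(binarize_counts(X, -1), "non-negative")

  # raising the threshold never turns an entry on
  withr::with_seed(5, {
    Y <- matrix(rpois(200, 2), 10, 20)
    for (th in 0:3) {
      B0 <- as.matrix(binarize_counts(Y, th))
      B1 <- as.matrix(binarize_counts(Y, th + 1))
      expect_true(all(B1 <= B0))
    }
  })
})

test_that("gene selection ranks by binomial variance, drops degenerate genes", {
  # detection frequencies 0.5, 0.1, 0.0 over 10 cells
  B <- rbind(rep(c(1, 0), 5), c(1, rep(0, 9)), rep(0, 10))
  expect_identical(select_genes_binomial_variance(B, ntop = 2), c(1L, 2L))
  expect_identical(select_genes_binomial_variance(B, ntop = 10), c(1L, 2L))
  # tie broken by smaller index
  B2 <- rbind(rep(c(1, 0), 5), rep(c(0, 1), 5), c(1, rep(0, 9)))
  expect_identical(select_genes_binomial_variance(B2, ntop = 2)[1], 1L)
  # all-degenerate input is an error
  expect_error(select_genes_binomial_variance(rbind(rep(1, 4), rep(0, 4)), 2),
               "positive binomial variance")
})

test_that("binomial upper tail is inclusive, exact on small cases, capped", {
  expect_equal(binom_neg_log_upper_tail(4, 4, 0.5), -log(1 / 16),
               tolerance = 1e-12)
  expect_equal(binom_neg_log_upper_tail(2, 3, 4 / 9), -log(304 / 729),
               tolerance = 1e-12)
  expect_identical(binom_neg_log_upper_tail(0, 50, 0.7), 0)
  expect_identical(binom_neg_log_upper_tail(0, 10, 0), 0)
  # degenerate q with k > 0: p-value 0, capped to the finite ceiling
  expect_equal(binom_neg_log_upper_tail(1, 5, 0), 745)
  expect_error(binom_neg_log_upper_tail(5, 4, 0.5), "k <= n")
  expect_error(binom_neg_log_upper_tail(1, 4, 1.5), "\\[0, 1\\]")

  # enumeration oracle on a grid of small cases
  for (n in c(1, 7, 23)) {
    for (q in c(0.05, 0.3, 0.77)) {
      got <- binom_neg_log_upper_tail(0:n, n, q)
      want <- vapply(0:n, enum_neg_log_upper_tail, numeric(1), n = n, q = q)
      expect_equal(got, want, tolerance = 1e-10)
    }
  }
})

test_that("pair scores reproduce the two-gene worked example", {
  B <- Matrix::Matrix(rbind(c(1, 0, 1), c(0, 1, 1)), sparse = TRUE)
  ps <- gene_pair_scores(B)
  expect_equal(ps$exactly_one_counts[1, 2], 2)
  expect_equal(ps$S[1, 2], -log(304 / 729), tolerance = 1e-12)
  expect_equal(ps$S[2, 1], ps$S[1, 2])
  expect_equal(diag(ps$S), c(0, 0))
  sc <- cxds_cell_scores(B, ps$S)
  expect_equal(sc, c(0, 0, 2 * -log(304 / 729)), tolerance = 1e-12)
})

test_that("co-expression is never penalized and degenerate pairs score zero", {
  # identical rows: exactly-one count 0 -> score 0
  B <- Matrix::Matrix(rbind(c(1, 0, 1, 0), c(1, 0, 1, 0)), sparse = TRUE)
  expect_equal(gene_pair_scores(B)$S[1, 2], 0)
  # q = 0 (both genes everywhere) with count 0: P(K >= 0) = 1
  B2 <- Matrix::Matrix(rbind(c(1, 1, 1), c(1, 1, 1), c(1, 0, 0)),
                       sparse = TRUE)
  expect_equal(gene_pair_scores(B2)$S[1, 2], 0)
})

test_that("fast diag(B'SB) equals the literal pair sum on random instances", {
  withr::with_seed(42, {
    for (rep in 1:20) {
      B <- random_binary_matrix(sample(5:30, 1), sample(10:80, 1))
      ps <- suppressMessages(gene_pair_scores(B))
      fast <- cxds_cell_scores(B, ps$S)
      expect_equal(fast, naive_cxds(B, ps$S), tolerance = 1e-10)
    }
  })
})

test_that("cxds is invariant to gene order and equivariant to cell order", {
  sim <- small_sim()
  # ntop covers every positive-variance gene, so the selected SET (and thus
  # the score) cannot depend on gene order
  fit <- cxds(sim$counts, ntop = 1000)
  perm_cells <- withr::with_seed(3, sample(ncol(sim$counts)))
  fit_p <- cxds(sim$counts[, perm_cells], ntop = 1000)
  expect_equal(fit_p$scores, fit$scores[perm_cells], tolerance = 1e-10)

  perm_genes <- withr::with_seed(4, sample(nrow(sim$counts)))
  fit_g <- cxds(sim$counts[perm_genes, ], ntop = 1000)
  expect_equal(fit_g$scores, fit$scores, tolerance = 1e-10)
})

test_that("cells expressing at most one selected gene score zero", {
  B <- Matrix::Matrix(rbind(c(1, 0, 1, 0), c(0, 1, 1, 0), c(1, 1, 0, 0)),
                      sparse = TRUE)
  ps <- gene_pair_scores(B)
  sc <- cxds_cell_scores(B, ps$S)
  expect_identical(sc[4], 0)
})

test_that("pair importance decomposes the squared scores and restricts to subsets", {
  B <- Matrix::Matrix(rbind(c(1, 0, 1), c(0, 1, 1)), sparse = TRUE)
  X <- as_count_matrix(as.matrix(B) * 3)  # counts binarize back to B
  fit <- cxds(X, ntop = 2)
  imp <- pair_importance(fit)
  s12 <- -log(304 / 729)
  expect_equal(imp[1, 2], (2 * s12) * s12, tolerance = 1e-12)
  expect_equal(sum(imp), sum(fit$scores^2), tolerance = 1e-12)
  # singleton subset of a zero-scoring cell: empty importance
  expect_true(all(pair_importance(fit, cells = 1) == 0))
  expect_error(pair_importance(fit, cells = 99), "out of range")

  # conservation on random data
  withr::with_seed(9, {
    for (rep in 1:10) {
      Br <- random_binary_matrix(12, 40)
      Xr <- as_count_matrix(as.matrix(Br))
      fr <- suppressMessages(cxds(Xr, ntop = 12))
      expect_equal(sum(pair_importance(fr)), sum(fr$scores^2),
                   tolerance = 1e-10)
    }
  })
})

test_that("top pairs are the strict upper triangle sorted by importance", {
  sim <- small_sim()
  fit <- cxds(sim$counts, ntop = 40)
  tp <- top_pairs(fit, n_pairs = 15)
  expect_equal(nrow(tp), 15)
  expect_true(all(diff(tp$importance) <= 0))
  expect_true(all(tp$gene_a != tp$gene_b))
  # asking for more pairs than exist returns them all
  tp_all <- top_pairs(fit, n_pairs = 1e6)
  expect_equal(nrow(tp_all), choose(40, 2))
  # the dominant pairs join markers of the two different types
  marker_type <- function(g) {
    i <- as.integer(sub("gene", "", g))
    ifelse(i <= 20, 1L, ifelse(i <= 40, 2L, NA_integer_))
  }
  expect_true(marker_type(tp$gene_a[1]) != marker_type(tp$gene_b[1]))
})

test_that("cxds tidiers return the documented shapes", {
  sim <- small_sim()
  fit <- cxds(sim$counts, ntop = 50)
  td <- tidy(fit)
  expect_named(td, c("barcode", "cxds_score", "cxds_rank"))
  expect_setequal(td$cxds_rank, seq_len(nrow(td)))
  expect_identical(td$cxds_score, cxds_score(sim$counts, ntop = 50)$cxds_score)
  gl <- glance(fit)
  expect_equal(gl$n_genes_selected, 50)
  expect_equal(gl$n_cells, ncol(sim$counts))
})
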