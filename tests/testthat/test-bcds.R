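test_that("log-variance gene selection orders genes and breaks ties by index", {
  X <- rbind(c(0, 0, 0), c(0, 5, 0))
  expect_identical(select_genes_logvar(X, ntop = 2), 2L)
  X2 <- rbind(c(0, 5, 0), c(0, 5, 0), c(0, 2, 0))
  expect_identical(select_genes_logvar(X2, ntop = 2), c(1L, 2L))
  expect_error(select_genes_logvar(rbind(c(1, 1), c(2, 2)), 2), "constant")
})

test_that("artificial doublets are sums of two distinct cells, reproducibly", {
  X <- as_count_matrix(cbind(c(1, 2), c(3, 4)),
                       gene_ids = c("g1", "g2"), barcodes = c("c1", "c2"))
  aug <- make_artificial_doublets(X, n_art = 4, seed = 1)
  expect_equal(dim(aug$counts), c(2L, 6L))
  expect_identical(aug$labels, c(0L, 0L, rep(1L, 4)))
  # with n = 2 every pair is {1, 2}: each doublet is c(4, 6)
  art <- as.matrix(aug$counts[, 3:6])
  expect_true(all(art == c(4, 6)))
  expect_true(all(aug$parent_pairs[, 1] != aug$parent_pairs[, 2]))

  sim <- small_sim()
  a1 <- make_artificial_doublets(sim$counts, seed = 7)
  a2 <- make_artificial_doublets(sim$counts, seed = 7)
  expect_identical(a1$parent_pairs, a2$parent_pairs)
  # doublet columns really are the parents' sums
  j <- 5L
  expect_equal(
    as.numeric(a1$counts[, ncol(sim$counts) + j]),
    as.numeric(sim$counts[, a1$parent_pairs[j, 1]] +
               sim$counts[, a1$parent_pairs[j, 2]])
  )
})

test_that("normalization centers log counts gene-wise over the augmented set", {
  counts <- rbind(c(0, exp(1) - 1), c(4, 4))
  f <- normalize_logcounts(counts)
  expect_equal(f[1, ], c(-0.5, 0.5), tolerance = 1e-12)
  expect_equal(f[2, ], c(0, 0))
  expect_equal(rowMeans(f), c(0, 0))
  expect_error(normalize_logcounts(matrix(-1, 2, 2)), "non-negative")
})

test_that("one-standard-error rule picks the simplest model within one SE", {
  expect_identical(choose_rounds_one_se(c(0.30, 0.20, 0.18, 0.19),
                                        rep(0.02, 4)), 2L)
  expect_identical(choose_rounds_one_se(c(0.3, 0.2, 0.1), c(0, 0, 0)), 3L)
  expect_identical(choose_rounds_one_se(0.4, 0.1), 1L)
  expect_error(choose_rounds_one_se(numeric(0), numeric(0)), "empty")
  expect_error(choose_rounds_one_se(c(0.1, 0.2), 0.1), "length")
})

test_that("bcds scores are probabilities, deterministic, and separate simulated doublets", {
  sim <- small_sim(seed = 21)
  fit <- bcds(sim$counts, ntop = 100, seed = 5)
  expect_true(all(fit$scores >= 0 & fit$scores <= 1))
  expect_length(fit$scores, ncol(sim$counts))
  expect_gte(auroc(fit$scores, sim$labels$is_doublet), 0.9)

  fit2 <- bcds(sim$counts, ntop = 100, seed = 5)
  expect_identical(fit$scores, fit2$scores)
  expect_identical(fit$n_rounds, fit2$n_rounds)

  expect_error(bcds(sim$counts), "seed")
})

test_that("fixed7 caps rounds at seven and tracks the CV heuristic", {
  sim <- small_sim(seed = 22)
  f7 <- bcds(sim$counts, ntop = 100, seed = 5, rounds_mode = "fixed7")
  expect_lte(f7$n_rounds, 7L)
  expect_null(f7$cv_log)
  expect_true(length(f7$train_error) <= 7)

  fcv <- bcds(sim$counts, ntop = 100, seed = 5)
  expect_s3_class(fcv$cv_log, "tbl_df")
  expect_identical(fcv$n_rounds,
                   choose_rounds_one_se(fcv$cv_log$error_mean,
                                        fcv$cv_log$error_se))
  # the two heuristics must agree on which cells look like doublets; the
  # global rank correlation is diluted by the arbitrary ordering of
  # near-zero singlet scores, so agreement is checked on the score values
  # and on the actual calls
  expect_gte(cor(f7$scores, fcv$scores), 0.8)
  k <- sum(sim$labels$is_doublet)
  overlap <- mean(call_top_k(f7$scores, k)[call_top_k(fcv$scores, k)])
  expect_gte(overlap, 0.6)
})

test_that("artificial doublets outscore singlets; null data stays calibrated", {
  sim <- small_sim(seed = 23)
  fit <- bcds(sim$counts, ntop = 100, seed = 9)
  n <- ncol(sim$counts)
  # artificial doublets vs true singlets among the original cells
  art_mean <- mean(fit$augmented_scores[-seq_len(n)])
  singlet_mean <- mean(fit$scores[!sim$labels$is_doublet])
  expect_gt(art_mean, singlet_mean)

  # one homogeneous cell type, no injected doublets: with balanced classes
  # the mean predicted probability over the augmented set stays near 1/2
  null_sim <- simulate_doublets(sim_config(n_types = 1, cells_per_type = 150,
                                           n_genes = 150,
                                           markers_per_type = 20,
                                           doublet_rate = 0, seed = 31))
  nf <- bcds(null_sim$counts, ntop = 100, seed = 13)
  expect_gt(mean(nf$augmented_scores), 0.3)
  expect_lt(mean(nf$augmented_scores), 0.7)
})

test_that("bcds tidiers and run log expose the fit", {
  sim <- small_sim(seed = 24)
  fit <- bcds(sim$counts, ntop = 80, seed = 3)
  td <- tidy(fit)
  expect_named(td, c("barcode", "bcds_score", "bcds_rank"))
  expect_setequal(td$bcds_rank, seq_len(nrow(td)))
  gl <- glance(fit)
  expect_identical(gl$n_rounds, fit$n_rounds)
  rl <- bcds_run_log(fit)
  expect_identical(rl$seed, 3)
  expect_identical(rl$n_rounds, fit$n_rounds)
  expect_type(rl$xgboost_version, "character")
})
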