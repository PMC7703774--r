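# Independent oracles used to verify the package's fast implementations.

# literal evaluation of the per-cell co-expression score: for each cell,
# sum S over all ordered pairs of genes the cell expresses
naive_cxds <- function(B, S) {
  B <- as.matrix(B)
  vapply(seq_len(ncol(B)), function(i) {
    idx <- which(B[, i] == 1)
    sum(S[idx, idx, drop = FALSE])
  }, numeric(1))
}

# term-by-term enumeration of -log P(K >= k), K ~ Bin(n, q), in log space.
# Whichever tail is smaller is enumerated directly (log-sum-exp); the other
# is obtained through log1p, so the result is accurate on both ends.
enum_neg_log_upper_tail <- function(k, n, q, cap = 745) {
  if (k == 0) return(0)
  if (q == 0) return(cap)
  if (q == 1) return(0)
  lterm <- function(i) lchoose(n, i) + i * log(q) + (n - i) * log1p(-q)
  lse <- function(v) {
    m <- max(v)
    m + log(sum(exp(v - m)))
  }
  upper <- lse(lterm(k:n))
  out <- if (upper > log(0.5)) {
    lower <- lse(lterm(0:(k - 1)))
    -log1p(-exp(lower))
  } else {
    -upper
  }
  min(out, cap)
}

# vectorized enumeration over all k = 0..n for one (n, q); returns the
# capped -log inclusive upper tail for every k
enum_neg_log_upper_tail_all_k <- function(n, q, cap = 745) {
  if (q == 0) return(c(0, rep(cap, n)))
  if (q == 1) return(rep(0, n + 1))
  i <- 0:n
  lt <- lchoose(n, i) + i * log(q) + (n - i) * log1p(-q)
  mx <- max(lt)
  upper <- mx + log(rev(cumsum(rev(exp(lt - mx)))))
  # refine far-tail entries where the global shift loses precision
  weak <- which(upper - mx < -600 | !is.finite(upper))
  for (j in weak) {
    tt <- lt[j:(n + 1)]
    m2 <- max(tt)
    upper[j] <- m2 + log(sum(exp(tt - m2)))
  }
  lower <- c(-Inf, mx + log(cumsum(exp(lt - mx)))[1:n])  # P(K <= k-1)
  lower <- pmin(lower, 0)  # rounding can push the log-probability above 0
  out <- ifelse(upper > log(0.5), -log1p(-exp(lower)), -upper)
  out[1] <- 0
  pmin(out, cap)
}

# tie-corrected Mann-Whitney AUROC via midranks
mw_auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# PR-curve threshold points (cumulative TP/FP, highest scores first),
# recomputed from scratch
pr_points_oracle <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(th, function(t) sum(labels[scores >= t]), numeric(1))
  fp <- vapply(th, function(t) sum(!labels[scores >= t]), numeric(1))
  cbind(tp = c(0, tp), fp = c(0, fp))
}

# numeric trapezoid integration of the Davis-Goadrich interpolant
dg_auprc_numeric <- function(scores, labels, n_grid = 4000) {
  labels <- as.logical(labels)
  pts <- pr_points_oracle(scores, labels)
  P <- sum(labels)
  area <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    tp_a <- pts[i, "tp"]; fp_a <- pts[i, "fp"]
    tp_b <- pts[i + 1, "tp"]; fp_b <- pts[i + 1, "fp"]
    if (tp_b == tp_a) next
    s <- (fp_b - fp_a) / (tp_b - tp_a)
    x <- seq(tp_a, tp_b, length.out = n_grid)
    prec <- ifelse(x == 0 & fp_a == 0, 1, x / (x + fp_a + s * (x - tp_a)))
    prec[x == 0 & fp_a > 0] <- 0
    area <- area + sum((prec[-1] + prec[-n_grid]) / 2 * diff(x))
  }
  unname(area / P)
}

# step-wise (conservative) and linear-interpolation (optimistic) PR areas,
# bracketing the DG area
auprc_bounds <- function(scores, labels) {
  labels <- as.logical(labels)
  pts <- pr_points_oracle(scores, labels)
  P <- sum(labels)
  lo <- 0
  hi <- 0
  for (i in seq_len(nrow(pts) - 1)) {
    tp_a <- pts[i, "tp"]; fp_a <- pts[i, "fp"]
    tp_b <- pts[i + 1, "tp"]; fp_b <- pts[i + 1, "fp"]
    if (tp_b == tp_a) next
    prec_a <- if (tp_a + fp_a == 0) 1 else tp_a / (tp_a + fp_a)
    prec_b <- tp_b / (tp_b + fp_b)
    w <- (tp_b - tp_a)
    lo <- lo + w * min(prec_a, prec_b)
    hi <- hi + w * max(prec_a, prec_b)
  }
  c(lower = unname(lo / P), upper = unname(hi / P))
}

# random sparse binary matrix with informative (non-degenerate) rows
random_binary_matrix <- function(m, n, p_range = c(0.05, 0.6)) {
  p <- stats::runif(m, p_range[1], p_range[2])
  B <- matrix(stats::rbinom(m * n, 1, rep(p, n)), nrow = m)
  Matrix::Matrix(B, sparse = TRUE)
}

# tiny deterministic count matrix used across IO tests
tiny_counts <- function() {
  as_count_matrix(matrix(c(5, 0, 0,
                           0, 0, 1,
                           2, 3, 4), nrow = 3, byrow = TRUE),
                  gene_ids = c("g1", "g2", "g3"),
                  barcodes = c("c1", "c2", "c3"))
}

small_sim <- function(seed = 11, doublet_rate = 0.1, ...) {
  simulate_doublets(sim_config(n_types = 2, cells_per_type = 80,
                               n_genes = 200, markers_per_type = 20,
                               doublet_rate = doublet_rate, seed = seed, ...))
}
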