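# Internal helpers shared across modules.

# Row-wise Pearson correlation between paired rows of two matrices.
# Rows with zero variance yield NA.
rowwise_cor <- function(x, y) {
  stopifnot(identical(dim(x), dim(y)))
  xc <- x - rowMeans(x)
  yc <- y - rowMeans(y)
  sx <- rowSums(xc^2)
  sy <- rowSums(yc^2)
  r <- rowSums(xc * yc) / sqrt(sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  # numerical guard: |r| can overshoot 1 by machine eps
  pmin(pmax(r, -1), 1)
}

# Two-sided p-value for a Pearson correlation under the t distribution
# with n - 2 degrees of freedom. |r| = 1 maps to p = 0 (analytic limit).
cor_pvalue <- function(r, n) {
  stopifnot(n >= 4)
  p <- rep(NA_real_, length(r))
  ok <- !is.na(r)
  at_unit <- ok & abs(r) >= 1 - 1e-15
  p[at_unit] <- 0
  mid <- ok & !at_unit
  tt <- r[mid] * sqrt(n - 2) / sqrt(1 - r[mid]^2)
  p[mid] <- 2 * pt(-abs(tt), df = n - 2)
  p
}

# Canonical unordered gene pair: lexicographically smaller id first, so the
# same pair always carries the same key regardless of input order.
canonical_pair <- function(a, b) {
  swap <- a > b
  gi <- ifelse(swap, b, a)
  gj <- ifelse(swap, a, b)
  list(gene_i = gi, gene_j = gj)
}

pair_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

# Mann-Whitney AUC of a score against binary truth (1 = positive class).
rank_auc <- function(score, truth) {
  truth <- as.integer(truth)
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC needs both classes present.")
  }
  r <- rank(score)
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Add-one permutation p-value: rank of the observed value in the null.
perm_pvalue <- function(observed, null_scores) {
  (1 + sum(null_scores >= observed)) / (length(null_scores) + 1)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 0 | x > 1)) {
    abort(sprintf("`%s` must lie in [0, 1].", name))
  }
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
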