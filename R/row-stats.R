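# Vectorized row-wise statistics used by per-gene selection. All SDs use
# the n-1 denominator. Validated against stats::t.test / var.test in the
# test suite.

row_means <- function(m) rowMeans(m)

row_vars <- function(m) {
  n <- ncol(m)
  if (n < 2) abort("need >= 2 columns for a variance")
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

row_sds <- function(m) sqrt(row_vars(m))

# Two-sample pooled (Student) or Welch t-test per row; two-sided p.
row_t_test <- function(a, b, pooled = TRUE) {
  n1 <- ncol(a); n2 <- ncol(b)
  m1 <- rowMeans(a); m2 <- rowMeans(b)
  v1 <- row_vars(a); v2 <- row_vars(b)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
    df <- (v1 / n1 + v2 / n2)^2 /
      ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  stat <- (m1 - m2) / se
  p <- 2 * pt(abs(stat), df, lower.tail = FALSE)
  # both groups constant and equal: no evidence of any difference
  p[se == 0 & m1 == m2] <- 1
  p[se == 0 & m1 != m2] <- 0
  list(statistic = stat, p_value = p, df = df)
}

# Brown-Forsythe/Levene-type two-sample Student t-test on absolute
# deviations from each group's replicate mean: tests a difference in
# replicate-level variability rather than in means.
row_levene_test <- function(a, b) {
  da <- abs(a - rowMeans(a))
  db <- abs(b - rowMeans(b))
  row_t_test(da, db, pooled = TRUE)
}

# One-sided variance-ratio F test (alternative: var(a) > var(b)).
row_var_f_test <- function(a, b) {
  v1 <- row_vars(a); v2 <- row_vars(b)
  stat <- v1 / v2
  p <- pf(stat, ncol(a) - 1, ncol(b) - 1, lower.tail = FALSE)
  p[v1 == 0 & v2 == 0] <- 1
  list(statistic = stat, p_value = p,
       df = cbind(ncol(a) - 1, ncol(b) - 1))
}

# Mean absolute off-diagonal Pearson correlation between rows of m
# (within-set) or between rows of a and rows of b (cross-set), computed
# over the given columns. Rows with zero variance yield undefined r and
# are excluded pair-wise; the number of excluded rows is returned.
abs_cor_matrix <- function(m) {
  keep <- row_sds(m) > 0
  r <- matrix(NA_real_, nrow(m), nrow(m),
              dimnames = list(rownames(m), rownames(m)))
  if (sum(keep) >= 2) {
    r[keep, keep] <- abs(cor(t(m[keep, , drop = FALSE])))
  }
  list(r = r, n_zero_var = sum(!keep))
}
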