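# Independent, straight-from-definition oracles. These deliberately share
# no code with the package internals they check.

# --- composite-index oracle: explicit loops over gene pairs -----------------
oracle_cluster_stats <- function(stage_mat, assignment, background_genes) {
  # stage_mat: genes x replicates; assignment: named integer (gene -> cluster)
  genes <- names(assignment)
  pair_abs_cor <- function(g1, g2) {
    x <- stage_mat[g1, ]; y <- stage_mat[g2, ]
    if (sd(x) == 0 || sd(y) == 0) return(NA_real_)
    abs(cor(x, y))
  }
  out <- lapply(sort(unique(assignment)), function(k) {
    members <- genes[assignment == k]
    outsiders <- setdiff(background_genes, members)
    sd_in <- mean(vapply(members, function(g) sd(stage_mat[g, ]), 0))
    rin <- c()
    if (length(members) >= 2) {
      for (i in seq_along(members)) for (j in seq_along(members)) {
        if (i < j) rin <- c(rin, pair_abs_cor(members[i], members[j]))
      }
    }
    pcc_in <- if (length(rin) == 0 || all(is.na(rin))) 0 else mean(rin, na.rm = TRUE)
    rout <- c()
    for (g in members) for (h in outsiders) {
      rout <- c(rout, pair_abs_cor(g, h))
    }
    pcc_out <- if (length(rout) == 0 || all(is.na(rout))) 0 else mean(rout, na.rm = TRUE)
    num <- sd_in * pcc_in
    ci <- if (pcc_out > 0) num / pcc_out else if (num > 0) Inf else 0
    data.frame(cluster = k, sd_in = sd_in, pcc_in_abs = pcc_in,
               pcc_out_abs = pcc_out, ci = ci)
  })
  do.call(rbind, out)
}

# --- TMM oracle: the published trimmed-mean-of-M-values definition ----------
oracle_tmm_factors <- function(m, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(m)
  f75 <- vapply(seq_len(ncol(m)), function(j) {
    unname(quantile(m[, j] / lib[j], 0.75))
  }, 0)
  ref <- which.min(abs(f75 - mean(f75)))
  one_factor <- function(j) {
    obs <- m[, j]; refv <- m[, ref]
    nO <- lib[j]; nR <- lib[ref]
    logR <- log2((obs / nO) / (refv / nR))
    absE <- (log2(obs / nO) + log2(refv / nR)) / 2
    v <- (nO - obs) / nO / obs + (nR - refv) / nR / refv
    fin <- is.finite(logR) & is.finite(absE) & (absE > -1e10)
    logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
    if (max(abs(logR)) < 1e-6) return(1)
    n <- length(logR)
    loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
    loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
    keep <- (rank(logR) >= loL & rank(logR) <= hiL) &
      (rank(absE) >= loS & rank(absE) <= hiS)
    f <- sum(logR[keep] / v[keep], na.rm = TRUE) / sum(1 / v[keep], na.rm = TRUE)
    if (!is.finite(f)) f <- 0
    2^f
  }
  f <- vapply(seq_len(ncol(m)), one_factor, 0)
  f / exp(mean(log(f)))
}

# --- exact-test oracles -----------------------------------------------------
# Two-sided Fisher p by full enumeration of tables with the observed margins,
# point-probability rule (with the standard 1 + 1e-7 relative guard against
# floating-point ties).
oracle_fisher_two_sided <- function(a, b, c, d) {
  K <- a + c          # reference-set size
  n <- a + b          # query size
  N <- a + b + c + d
  ks <- max(0, n - (N - K)):min(n, K)
  probs <- dhyper(ks, K, N - K, n)
  p0 <- dhyper(a, K, N - K, n)
  sum(probs[probs <= p0 * (1 + 1e-7)])
}

oracle_hyper_upper <- function(k, N, K, n) {
  ks <- max(0, n - (N - K)):min(n, K)
  sum(dhyper(ks[ks >= k], K, N - K, n))
}

# --- Benjamini-Hochberg oracle: literal step-up rule ------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(p[o][i:m] * m / (i:m), 1)
  }
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# --- small constructed fixtures ---------------------------------------------
# A 2-stage design with r replicates each, stages FR4 (reference) and FR8.
toy_design <- function(r = 3, stages = c("FR4", "FR8")) {
  stage_design(tibble::tibble(
    sample = paste0(rep(stages, each = r), "_r", rep(seq_len(r), length(stages))),
    stage = rep(stages, each = r),
    replicate = rep(seq_len(r), length(stages))
  ), reference = stages[1])
}

toy_expr <- function(values, r = 3, stages = c("FR4", "FR8")) {
  expression_matrix(values, toy_design(r = r, stages = stages))
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))
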