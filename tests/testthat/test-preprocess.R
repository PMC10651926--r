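test_that("TMM factors: identity, pure depth scaling, and invariance", {
  set.seed(7)
  m <- matrix(rpois(40, 50) + 1, 10, 4,
              dimnames = list(paste0("g", 1:10), paste0("s", 1:4)))
  same <- m[, c(1, 1, 1)]
  colnames(same) <- paste0("s", 1:3)
  f_same <- tmm_factors(same)
  expect_equal(f_same$factor, rep(1, 3), tolerance = 1e-9)

  depth <- cbind(s1 = m[, 1], s2 = 2L * m[, 1])
  f_depth <- tmm_factors(depth)
  expect_equal(f_depth$factor, rep(1, 2), tolerance = 1e-9)

  # multiplying one sample by a constant leaves every M and A value unchanged
  # and moves only the library size; the factor itself shifts marginally
  # because the precision weights of the weighted trimmed mean depend on
  # absolute counts
  m2 <- m; m2[, 2] <- m2[, 2] * 3L
  f1 <- tmm_factors(m); f2 <- tmm_factors(m2)
  expect_equal(f2$factor, f1$factor, tolerance = 0.01)
  expect_equal(f2$lib_size[2], 3 * f1$lib_size[2])

  # geometric mean of the factors is 1
  expect_equal(exp(mean(log(f1$factor))), 1, tolerance = 1e-9)

  bad <- m; bad[, 3] <- 0L
  expect_error(tmm_factors(bad), "all-zero")
})

test_that("TMM factors match the from-definition oracle", {
  # 5-gene, 3-sample toy with one inflated gene
  toy <- matrix(c(10, 20, 30, 40, 50,
                  12, 18, 33, 41, 300,
                  9, 22, 28, 44, 48), 5, 3,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  expect_equal(tmm_factors(toy)$factor, oracle_tmm_factors(toy),
               tolerance = 1e-10)
  # and on larger random count matrices
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rnbinom(600, mu = 100 * exp(rnorm(100)), size = 5), 100, 6)
    dimnames(m) <- list(paste0("g", 1:100), paste0("s", 1:6))
    m <- m[rowSums(m > 0) == 6, ]
    expect_equal(tmm_factors(m)$factor, oracle_tmm_factors(m),
                 tolerance = 1e-10)
  }
})

test_that("GeTMM arithmetic follows its definition", {
  # single sample: lengths 1000/2000 with counts 10/20 give equal RPK and
  # GeTMM 5e5 each
  cm <- count_matrix(matrix(c(10, 20), 2, 1,
                            dimnames = list(c("g1", "g2"), "s1")),
                     c(g1 = 1000, g2 = 2000))
  g <- getmm_normalize(cm)
  expect_equal(unname(as.matrix(g)[, 1]), c(5e5, 5e5))

  set.seed(3)
  counts <- matrix(rpois(60, 40) + 1, 20, 3,
                   dimnames = list(paste0("g", 1:20), paste0("s", 1:3)))
  lens <- setNames(runif(20, 500, 4000), paste0("g", 1:20))
  cm <- count_matrix(counts, lens)
  g <- getmm_normalize(cm)
  f <- attr(g, "factors")
  # per-sample totals are 1e6 / factor
  expect_equal(unname(colSums(as.matrix(g))), 1e6 / f$factor,
               tolerance = 1e-6)
  # unit factors reduce GeTMM to RPK-CPM
  rpk <- counts / (lens / 1000)
  f1 <- f; f1$factor <- rep(1, 3)
  g1 <- getmm_normalize(cm, factors = f1)
  expect_equal(as.matrix(g1), sweep(rpk, 2, colSums(rpk), "/") * 1e6)
  # doubling lengths halves RPK but leaves GeTMM unchanged
  cm2 <- count_matrix(counts, lens * 2)
  expect_equal(as.matrix(getmm_normalize(cm2)), as.matrix(g),
               tolerance = 1e-12)
})

test_that("low-expression filter removes any-sample zeros and is idempotent", {
  m <- rbind(g1 = c(0, 5, 5, 5, 5, 5),
             g2 = c(0.1, 2, 2, 2, 2, 2),
             g3 = c(3, 3, 3, 3, 3, 3))
  colnames(m) <- paste0(rep(c("FR4", "FR8"), each = 3), "_r", rep(1:3, 2))
  expr <- toy_expr(m)
  out <- quiet(filter_low_expression(expr))
  expect_setequal(gene_ids(out), c("g2", "g3"))       # log2(1.1) > 0 retained
  expect_identical(attr(out, "removed_genes"), "g1")
  out2 <- quiet(filter_low_expression(out))
  expect_identical(as.matrix(out2), as.matrix(out))   # idempotent
  # strict-literal mode removes GeTMM <= 0.5
  strict <- quiet(filter_low_expression(expr, mode = "strict_literal"))
  expect_setequal(gene_ids(strict), "g3")
  # all-positive matrix passes unchanged
  all_pos <- quiet(filter_low_expression(toy_expr(m[3, , drop = FALSE])))
  expect_identical(dim(all_pos), c(1L, 6L))
})

test_that("stage statistics and CV behave as defined", {
  m <- rbind(g1 = c(2, 2, 2, 1, 2, 3),
             g2 = c(1, 2, 3, 4, 5, 6),
             g3 = c(-1, -2, -3, 1, 2, 3))
  colnames(m) <- paste0(rep(c("FR4", "FR8"), each = 3), "_r", rep(1:3, 2))
  st <- quiet(stage_stats(toy_expr(m)))
  g1 <- st[st$gene_id == "g1", ]
  expect_equal(g1$sd[g1$stage == "FR4"], 0)
  expect_equal(g1$cv[g1$stage == "FR4"], 0)
  expect_equal(g1$mean[g1$stage == "FR8"], 2)
  expect_equal(g1$sd[g1$stage == "FR8"], 1)
  expect_equal(g1$cv[g1$stage == "FR8"], 0.5)
  # negative mean -> CV flagged undefined
  expect_true(is.na(st$cv[st$gene_id == "g3" & st$stage == "FR4"]))
  # CV scale invariance
  m2 <- m; m2["g2", ] <- m2["g2", ] * 7
  st2 <- quiet(stage_stats(toy_expr(m2)))
  expect_equal(st2$cv[st2$gene_id == "g2"], st$cv[st$gene_id == "g2"])
})

test_that("CV comparison is a symmetric rank-sum test with median difference", {
  set.seed(5)
  n <- 60
  m <- matrix(abs(rnorm(n * 6, 10, 1)), n, 6,
              dimnames = list(paste0("g", 1:n), NULL))
  colnames(m) <- paste0(rep(c("FR4", "FR8"), each = 3), "_r", rep(1:3, 2))
  st <- quiet(stage_stats(toy_expr(m)))
  res_ab <- compare_cv(st, "FR4", "FR8")
  res_ba <- compare_cv(st, "FR8", "FR4")
  expect_equal(res_ab$p_value, res_ba$p_value)
  expect_equal(res_ab$median_diff, -res_ba$median_diff)
  # identical CV vectors -> p = 1, median diff 0
  st_same <- st
  st_same$cv[st_same$stage == "FR8"] <- st_same$cv[st_same$stage == "FR4"]
  same <- compare_cv(st_same, "FR4", "FR8")
  expect_equal(same$p_value, 1)
  expect_equal(same$median_diff, 0)
  # a clean +1 shift is detected
  st_shift <- st
  st_shift$cv[st_shift$stage == "FR8"] <- st_shift$cv[st_shift$stage == "FR4"] + 1
  shift <- compare_cv(st_shift, "FR4", "FR8")
  expect_equal(shift$median_diff, 1)
  expect_lt(shift$p_value, 0.05)
  expect_error(compare_cv(st[st$gene_id %in% paste0("g", 1:6), ],
                          "FR4", "FR8"), ">= 10")
})

test_that("sample PCA separates groups, fixes signs, and normalizes variance", {
  set.seed(9)
  n <- 100
  base <- matrix(rnorm(n * 6, 5, 0.2), n, 6)
  base[1:40, 4:6] <- base[1:40, 4:6] + 2      # separated second stage
  dimnames(base) <- list(paste0("g", 1:n), NULL)
  colnames(base) <- paste0(rep(c("FR4", "FR8"), each = 3), "_r", rep(1:3, 2))
  pc <- pca_samples(toy_expr(base))
  expect_equal(sum(pc$var_explained), 1)
  # PC1 separates the stages cleanly (every FR8 score beyond every FR4 score)
  s1 <- pc$scores$PC1[pc$scores$stage == "FR4"]
  s2 <- pc$scores$PC1[pc$scores$stage == "FR8"]
  expect_true(max(s1) < min(s2) || max(s2) < min(s1))
  # sign convention: largest-|loading| convention makes scores reproducible
  pc2 <- pca_samples(toy_expr(base))
  expect_identical(pc$scores, pc2$scores)
  # duplicated sample -> identical scores
  dup <- base[, c(1:6, 1)]
  colnames(dup)[7] <- "FR4_r4"
  d7 <- stage_design(tibble::tibble(
    sample = colnames(dup), stage = rep(c("FR4", "FR8", "FR4"), c(3, 3, 1)),
    replicate = c(1:3, 1:3, 4)))
  pc3 <- pca_samples(expression_matrix(dup, d7))
  expect_equal(unlist(pc3$scores[1, -(1:3)]), unlist(pc3$scores[7, -(1:3)]),
               tolerance = 1e-8)
  expect_error(pca_samples(toy_expr(matrix(1, 4, 6,
    dimnames = list(paste0("g", 1:4), colnames(base))))), "constant")
})

test_that("sample clustering recovers tight groups and ignores input order", {
  set.seed(2)
  n <- 50
  m <- matrix(rnorm(n * 6, 0, 0.1), n, 6)
  m[, 4:6] <- m[, 4:6] + 5
  dimnames(m) <- list(paste0("g", 1:n), NULL)
  colnames(m) <- paste0(rep(c("FR4", "FR8"), each = 3), "_r", rep(1:3, 2))
  cl <- cluster_samples(toy_expr(m), k = 2)
  lab <- cl$labels
  expect_identical(length(unique(lab$cluster[grepl("FR4", lab$sample)])), 1L)
  expect_identical(length(unique(lab$cluster[grepl("FR8", lab$sample)])), 1L)
  expect_false(lab$cluster[1] == lab$cluster[6])
  # permutation invariance up to label renaming
  perm <- sample(6)
  cl2 <- cluster_samples(expression_matrix(m[, perm], toy_design(3)), k = 2)
  lab2 <- cl2$labels
  merged <- merge(lab, lab2, by = "sample")
  expect_identical(length(unique(paste(merged$cluster.x, merged$cluster.y))), 2L)
  # identical samples merge at height zero
  same <- m[, c(1, 1, 2)]
  colnames(same) <- c("a", "b", "c")
  d3 <- stage_design(tibble::tibble(sample = c("a", "b", "c"),
                                    stage = c("A", "A", "A"),
                                    replicate = 1:3))
  cl3 <- cluster_samples(expression_matrix(same, d3))
  expect_equal(min(cl3$tree$height), 0)
  # newick export is readable by ape
  nw <- withr::local_tempfile(fileext = ".nwk")
  write_newick(cl, nw)
  expect_s3_class(ape::read.tree(nw), "phylo")
})
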