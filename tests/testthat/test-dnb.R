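make_candidates <- function(genes, stage = "FR8") {
  tibble::tibble(gene_id = genes, stage = stage, p_value = 0.01,
                 q_value = 0.01, fc_sd = 3, selected = TRUE)
}

test_that("gene clustering recovers planted correlation blocks", {
  r <- 4
  base1 <- c(1, 2, 3, 4); base2 <- c(4, 1, 3, 2)
  block1 <- t(sapply(1:5, function(i) i + 2 * base1))   # perfectly correlated
  block2 <- t(sapply(1:5, function(i) i - base2))
  m <- rbind(block1, block2)
  rownames(m) <- paste0("g", 1:10)
  ref <- matrix(rnorm(10 * r, 2, 1), 10, r)
  full <- cbind(ref, m)
  colnames(full) <- paste0(rep(c("FR4", "FR8"), each = r), "_r", rep(1:r, 2))
  expr <- toy_expr(full, r = r)
  cl <- cluster_genes(expr, make_candidates(paste0("g", 1:10)), "FR8", k = 2)
  expect_identical(length(unique(cl$cluster[1:5])), 1L)
  expect_identical(length(unique(cl$cluster[6:10])), 1L)
  expect_false(cl$cluster[1] == cl$cluster[10])

  # K = number of candidates -> singletons
  cl_single <- cluster_genes(expr, make_candidates(paste0("g", 1:10)),
                             "FR8", k = 10)
  expect_identical(sort(unique(cl_single$cluster)), 1:10)

  # permutation invariance up to relabeling
  perm <- c(7, 3, 10, 1, 5, 9, 2, 8, 4, 6)
  expr_p <- toy_expr(full[perm, ], r = r)
  cl_p <- cluster_genes(expr_p, make_candidates(rownames(full)[perm]),
                        "FR8", k = 2)
  merged <- dplyr::inner_join(cl, cl_p, by = "gene_id")
  expect_identical(length(unique(paste(merged$cluster.x, merged$cluster.y))), 2L)

  # too few candidates for K errors, unless allow_small_k
  expect_error(cluster_genes(expr, make_candidates(paste0("g", 1:3)),
                             "FR8", k = 5), "smaller k")
  cl_small <- cluster_genes(expr, make_candidates(paste0("g", 1:3)),
                            "FR8", k = 5, allow_small_k = TRUE)
  expect_identical(attr(cl_small, "k"), 3L)
})

test_that("cluster statistics match the brute-force oracle on a toy case", {
  set.seed(17)
  r <- 3
  m <- matrix(rnorm(6 * r, 5, 2), 6, r)
  rownames(m) <- paste0("g", 1:6)
  full <- cbind(matrix(rnorm(6 * r), 6, r), m)
  colnames(full) <- paste0(rep(c("FR4", "FR8"), each = r), "_r", rep(1:r, 2))
  expr <- toy_expr(full, r = r)
  assignment <- setNames(c(1L, 1L, 1L, 2L, 2L, 2L), paste0("g", 1:6))
  clustering <- tibble::tibble(gene_id = names(assignment), stage = "FR8",
                               cluster = unname(assignment))
  got <- dnb_cluster_stats(expr, clustering, background = "candidates")
  want <- oracle_cluster_stats(m, assignment, names(assignment))
  expect_equal(got$sd_in, want$sd_in, tolerance = 1e-10)
  expect_equal(got$pcc_in_abs, want$pcc_in_abs, tolerance = 1e-10)
  expect_equal(got$pcc_out_abs, want$pcc_out_abs, tolerance = 1e-10)
  expect_equal(got$ci, want$ci, tolerance = 1e-10)
  # all_genes background matches the oracle with the full gene universe
  got_all <- dnb_cluster_stats(expr, clustering, background = "all_genes")
  want_all <- oracle_cluster_stats(stage_values(expr, "FR8"), assignment,
                                   rownames(full))
  expect_equal(got_all$pcc_out_abs, want_all$pcc_out_abs, tolerance = 1e-10)
})

test_that("cluster statistics handle degenerate members", {
  r <- 3
  m <- rbind(g1 = c(1, 1, 1), g2 = c(2, 2, 2),  # constant cluster
             g3 = c(1, 2, 3), g4 = c(2, 4, 6))
  full <- cbind(matrix(0, 4, r), m)
  rownames(full) <- rownames(m)
  colnames(full) <- paste0(rep(c("FR4", "FR8"), each = r), "_r", rep(1:r, 2))
  expr <- toy_expr(full, r = r)
  clustering <- tibble::tibble(gene_id = paste0("g", 1:4), stage = "FR8",
                               cluster = c(1L, 1L, 2L, 2L))
  st <- quiet(dnb_cluster_stats(expr, clustering))
  c1 <- st[st$cluster == 1, ]
  expect_equal(c1$sd_in, 0)       # constant members
  expect_equal(c1$ci, 0)          # SD_in = 0 forces CI = 0
  c2 <- st[st$cluster == 2, ]
  expect_equal(c2$pcc_in_abs, 1)  # proportional genes correlate perfectly
  # constant outsiders contribute no defined pairs; remaining pairs drive
  # PCC_out; zero-variance genes are counted
  expect_identical(attr(st, "n_zero_var_genes"), 2L)
  # singleton clusters carry no within-group evidence: PCC_in = 0, CI = 0
  singles <- tibble::tibble(gene_id = paste0("g", 3:4), stage = "FR8",
                            cluster = 1:2)
  st_single <- quiet(dnb_cluster_stats(expr, singles))
  expect_equal(st_single$pcc_in_abs, c(0, 0))
  expect_equal(st_single$ci, c(0, 0))
})

test_that("composite index identities and invariances hold", {
  expect_equal(composite_index(1, 1, 1), 1)
  expect_equal(composite_index(0, 1, 0.5), 0)
  expect_identical(composite_index(2, 0.5, 0), Inf)
  expect_equal(composite_index(0, 0, 0), 0)

  # scaling a stage by c > 0 scales SD_in (hence CI) by c and leaves the
  # correlation terms unchanged
  set.seed(23)
  r <- 4
  for (i in 1:5) {
    m <- matrix(rnorm(8 * 2 * r), 8, 2 * r,
                dimnames = list(paste0("g", 1:8), NULL))
    colnames(m) <- paste0(rep(c("FR4", "FR8"), each = r), "_r", rep(1:r, 2))
    cl <- tibble::tibble(gene_id = paste0("g", 1:8), stage = "FR8",
                         cluster = rep(1:2, each = 4))
    s1 <- dnb_cluster_stats(toy_expr(m, r = r), cl)
    m2 <- m; m2[, grepl("FR8", colnames(m))] <- m2[, grepl("FR8", colnames(m))] * 3
    s2 <- dnb_cluster_stats(toy_expr(m2, r = r), cl)
    expect_equal(s2$sd_in, 3 * s1$sd_in)
    expect_equal(s2$pcc_in_abs, s1$pcc_in_abs)
    expect_equal(s2$pcc_out_abs, s1$pcc_out_abs)
    expect_equal(s2$ci, 3 * s1$ci)
    # invariance to cluster relabeling and gene order
    perm <- sample(8)
    cl_p <- tibble::tibble(gene_id = paste0("g", perm), stage = "FR8",
                           cluster = 3 - cl$cluster[perm])
    s3 <- dnb_cluster_stats(toy_expr(m, r = r), cl_p)
    expect_equal(sort(s3$ci), sort(s1$ci))
  }
})

test_that("cross-cluster pair accounting covers each pair exactly twice", {
  # with background = candidates, summing member x outsider pairs over all
  # clusters double-counts each unordered cross-cluster pair
  set.seed(29)
  sizes <- c(3, 5, 2, 4)
  assignment <- rep(seq_along(sizes), sizes)
  n <- sum(sizes)
  n_pairs <- sum(vapply(seq_along(sizes), function(k) {
    sizes[k] * (n - sizes[k])
  }, 0))
  cross_pairs <- (n^2 - sum(sizes^2)) / 2
  expect_identical(n_pairs, 2 * cross_pairs)
})

test_that("DNB selection takes per-stage argmax CI and breaks ties early", {
  stats <- tibble::tibble(
    stage = rep(c("FR8", "IR8", "SR8"), each = 2),
    cluster = rep(1:2, 3),
    n_genes = 2L,
    sd_in = 1, pcc_in_abs = 0.5,
    pcc_out_abs = 0.5,
    ci = c(0.2, 0.1, 1.7, 0.3, 0.4, 0.2),
    ci_infinite = FALSE
  )
  assignments <- tibble::tibble(
    gene_id = paste0("g", 1:6),
    stage = rep(c("FR8", "IR8", "SR8"), each = 2),
    cluster = rep(1L, 6)
  )
  res <- select_dnb(stats, assignments, stage_order = c("FR8", "IR8", "SR8"))
  expect_identical(res$tipping_stage, "IR8")
  expect_identical(res$dnb_genes, c("g3", "g4"))
  expect_equal(tidy(res)$ci, c(0.2, 1.7, 0.4))
  expect_identical(glance(res)$n_dnb_genes, 2L)

  # tie across stages: earlier stage in design order wins
  stats_tie <- stats
  stats_tie$ci <- c(1.7, 0.1, 1.7, 0.3, 0.4, 0.2)
  res_tie <- quiet(select_dnb(stats_tie, assignments,
                              stage_order = c("FR8", "IR8", "SR8")))
  expect_identical(res_tie$tipping_stage, "FR8")
  # tie within a stage: lower cluster index wins
  stats_tie2 <- stats
  stats_tie2$ci <- c(0.5, 0.5, 0.1, 0.1, 0.1, 0.1)
  res_tie2 <- quiet(select_dnb(stats_tie2, assignments,
                               stage_order = c("FR8", "IR8", "SR8")))
  expect_identical(res_tie2$trajectory$cluster[1], 1L)

  # all-zero CI -> explicit no-signal result
  stats0 <- stats; stats0$ci <- 0
  res0 <- quiet(select_dnb(stats0, assignments,
                           stage_order = c("FR8", "IR8", "SR8")))
  expect_true(res0$no_signal)
  expect_identical(res0$dnb_genes, character(0))
  expect_true(is.na(glance(res0)$tipping_stage))
})

test_that("the full analysis recovers a planted transition end to end", {
  run_one <- function(seed) {
    spec <- simulation_spec(n_genes = 2250, dnb_module_size = 50,
                            deg_set_size = 200, replicates_per_stage = 5,
                            seed = seed)
    sim <- simulate_experiment(spec)
    res <- quiet(dnb_analysis(sim$expr, k = 40))
    list(res = res, met = recovery_metrics(res, sim$truth))
  }
  runs <- purrr::map(401:403, run_one)
  mets <- purrr::map_dfr(runs, "met")
  expect_true(all(mets$stage_correct))
  # the winning cluster is dominated by planted module genes; its exact
  # extent fluctuates with the 5-point correlation estimates
  expect_gt(median(mets$jaccard), 0.15)
  expect_gt(median(mets$precision), 0.7)
  # autoplot returns a ggplot of the CI trajectory
  expect_s3_class(autoplot(runs[[1]]$res), "ggplot")
})
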