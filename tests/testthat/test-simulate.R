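test_that("simulation specs validate their parameters", {
  expect_error(simulation_spec(n_genes = 100, dnb_module_size = 80,
                               deg_set_size = 40), "exceed")
  expect_error(simulation_spec(tipping_stage = "FR4"), "differ")
  expect_error(simulation_spec(tipping_stage = "XX"), "tipping_stage")
  expect_error(simulation_spec(within_correlation = 1), "within_correlation")
  expect_error(simulation_spec(variance_inflation = 0.5), "variance_inflation")
  expect_error(simulation_spec(replicates_per_stage = 1), "replicates")
})

test_that("the generator is reproducible and honours its spec", {
  spec <- simulation_spec(n_genes = 300, dnb_module_size = 20,
                          deg_set_size = 30, seed = 99)
  s1 <- simulate_experiment(spec)
  s2 <- simulate_experiment(spec)
  expect_identical(as.matrix(s1$expr), as.matrix(s2$expr))
  expect_identical(s1$truth$dnb_genes, s2$truth$dnb_genes)
  expect_identical(dim(s1$expr), c(300L, 12L))
  expect_identical(length(s1$truth$dnb_genes), 20L)
  expect_identical(length(s1$truth$deg_genes), 30L)
  expect_identical(s1$truth$tipping_stage, "FR8")
  # a different seed gives different data
  s3 <- simulate_experiment(simulation_spec(n_genes = 300,
                                            dnb_module_size = 20,
                                            deg_set_size = 30, seed = 100))
  expect_false(identical(as.matrix(s1$expr), as.matrix(s3$expr)))
})

test_that("planted moments match their targets at large replicate counts", {
  spec <- simulation_spec(n_genes = 400, dnb_module_size = 40,
                          deg_set_size = 40, replicates_per_stage = 30,
                          variance_inflation = 3, within_correlation = 0.8,
                          baseline_sd = 0.5, seed = 7)
  sim <- simulate_experiment(spec)
  tip <- stage_values(sim$expr, "FR8")[sim$truth$dnb_genes, ]
  # empirical module SD ~ f * sigma0 (relative error < 15%)
  expect_lt(abs(mean(dnbtip:::row_sds(tip)) - 1.5) / 1.5, 0.15)
  # empirical mean pairwise correlation ~ rho +/- 0.1
  cm <- cor(t(tip))
  expect_lt(abs(mean(cm[upper.tri(cm)]) - 0.8), 0.1)
  # DEG genes: shifted mean, baseline variance
  deg_tip <- stage_values(sim$expr, "FR8")[sim$truth$deg_genes, ]
  deg_ref <- stage_values(sim$expr, "FR4")[sim$truth$deg_genes, ]
  expect_lt(abs(mean(rowMeans(deg_tip) - rowMeans(deg_ref)) - 2), 0.2)
  expect_lt(abs(mean(dnbtip:::row_sds(deg_tip)) - 0.5) / 0.5, 0.15)
  # module genes behave as background at non-tipping stages
  other <- stage_values(sim$expr, "IR8")[sim$truth$dnb_genes, ]
  expect_lt(abs(mean(dnbtip:::row_sds(other)) - 0.5) / 0.5, 0.15)
})

test_that("a null configuration produces no or a flat transition signal", {
  flat <- 0L
  n_seeds <- 10
  for (seed in seq_len(n_seeds)) {
    spec <- simulation_spec(n_genes = 800, dnb_module_size = 40,
                            deg_set_size = 0, variance_inflation = 1,
                            within_correlation = 0, deg_mean_shift = 0,
                            seed = seed)
    sim <- simulate_experiment(spec)
    res <- quiet(dnb_analysis(sim$expr))
    ok <- res$no_signal ||
      max(res$trajectory$ci) / median(res$trajectory$ci) < 2
    flat <- flat + ok
  }
  expect_gte(flat / n_seeds, 0.9)
})

test_that("recovery metrics compute Jaccard, precision and recall", {
  truth <- structure(list(dnb_genes = paste0("g", 1:10),
                          deg_genes = character(0),
                          tipping_stage = "FR8",
                          gene_ids = paste0("g", 1:100)),
                     class = "simulated_truth")
  mk <- function(genes, stage) {
    structure(list(dnb_genes = genes, tipping_stage = stage,
                   trajectory = tibble::tibble(), no_signal = FALSE),
              class = "dnb_result")
  }
  ident <- recovery_metrics(mk(paste0("g", 1:10), "FR8"), truth)
  expect_equal(ident$jaccard, 1)
  expect_true(ident$stage_correct)
  disjoint <- recovery_metrics(mk(paste0("g", 11:20), "IR8"), truth)
  expect_equal(disjoint$jaccard, 0)
  expect_false(disjoint$stage_correct)
  half <- recovery_metrics(mk(paste0("g", c(1:5, 11:15)), "FR8"), truth)
  expect_equal(half$jaccard, 5 / 15)
  expect_equal(half$precision, 0.5)
  expect_equal(half$recall, 0.5)
})

test_that("stage recovery does not degrade as variance inflation grows", {
  # recovery rate over seeds should be non-decreasing in f (tolerance: one
  # flip), using a compact design so the check stays fast
  fs <- c(1, 2, 3, 4)
  n_seeds <- 25
  rate <- vapply(fs, function(f) {
    hits <- vapply(seq_len(n_seeds), function(seed) {
      spec <- simulation_spec(n_genes = 600, dnb_module_size = 40,
                              deg_set_size = 60, replicates_per_stage = 4,
                              variance_inflation = f, seed = 1000 + seed)
      sim <- simulate_experiment(spec)
      res <- quiet(dnb_analysis(sim$expr, k = 30))
      identical(res$tipping_stage, sim$truth$tipping_stage)
    }, logical(1))
    mean(hits)
  }, numeric(1))
  # allow a single adjacent inversion of at most one seed (1/n_seeds)
  viol <- sum(pmax(0, -diff(rate)) > 1 / n_seeds + 1e-9)
  expect_lte(viol, 0)
  expect_gt(rate[4], rate[1])
})

test_that("simulated regulatory edges place DNB genes upstream of DEGs", {
  spec <- simulation_spec(n_genes = 500, dnb_module_size = 30,
                          deg_set_size = 60, seed = 5)
  sim <- simulate_experiment(spec)
  edges <- simulate_trn(sim$truth, n_extra_edges = 100, p_dnb_deg = 1,
                        seed = 5)
  planted <- edges[edges$tf %in% sim$truth$dnb_genes &
                     edges$target %in% sim$truth$deg_genes, ]
  expect_gte(length(unique(planted$target)), 55)  # nearly every DEG wired
  # reproducible
  edges2 <- simulate_trn(sim$truth, n_extra_edges = 100, p_dnb_deg = 1,
                         seed = 5)
  expect_identical(edges, edges2)
  # zero planted and zero extra edges give an empty artifact
  none <- simulate_trn(sim$truth, n_extra_edges = 0, p_dnb_deg = 0, seed = 5)
  expect_identical(nrow(none), 0L)
  net <- quiet(suppressWarnings(
    build_network(none, dnb = sim$truth$dnb_genes,
                  deg = sim$truth$deg_genes)))
  expect_identical(nrow(net$nodes), 0L)
})

test_that("simulated gene sets show no DNB association unless enriched", {
  spec <- simulation_spec(n_genes = 800, dnb_module_size = 40,
                          deg_set_size = 40, seed = 8)
  sim <- simulate_experiment(spec)
  # null enrichment: OR ~ 1 on average over seeds
  ors <- vapply(1:12, function(s) {
    gs <- simulate_genesets(sim$truth, sizes = c(setA = 200), enrichment = 1,
                            seed = s)
    overlap_odds_ratio(sim$truth$dnb_genes, gs$collection$setA,
                       sim$truth$gene_ids)$odds_ratio
  }, numeric(1))
  expect_lt(abs(mean(ors) - 1), 0.35)
  # heavy enrichment: OR >> 1
  gs_hi <- simulate_genesets(sim$truth, sizes = c(setA = 200),
                             enrichment = 30, seed = 1)
  or_hi <- overlap_odds_ratio(sim$truth$dnb_genes, gs_hi$collection$setA,
                              sim$truth$gene_ids)$odds_ratio
  expect_gt(or_hi, 3)
  # default sizes are truncated to the gene count and stay valid
  gs_def <- simulate_genesets(sim$truth, seed = 2)
  expect_true(all(lengths(gs_def$collection) <= 800))
  expect_true(all(c("gene", "term", "name", "namespace") %in%
                    names(gs_def$go_annotations)))
})
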