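#' Parameters of a synthetic staged expression experiment
#'
#' The generator emulates the structure of a staged, replicated
#' transcriptome experiment with a planted DNB module: a background of
#' uncorrelated genes with stage-stable variance; a module of `m` genes
#' whose replicate variance is inflated by `f` and which share pairwise
#' correlation `rho_in` at exactly the tipping stage (single shared
#' Gaussian factor per sample, so target SD and correlation hold in
#' expectation); and a DEG-like set whose mean is shifted by `delta` at
#' every non-reference stage with unchanged variance. Defaults mirror the
#' four-stage (FR4/FR8/IR8/SR8) triplicate layout of the cassava
#' storage-root system, with the transition planted at FR8.
#'
#' @param n_genes Total number of genes (default 4000).
#' @param stages Stage labels (default `c("FR4","FR8","IR8","SR8")`).
#' @param replicates_per_stage Biological replicates per stage (default 3).
#' @param reference_stage Reference (default first stage).
#' @param tipping_stage Stage carrying the planted module (default second
#'   stage).
#' @param dnb_module_size Planted module size m (default 60).
#' @param variance_inflation SD inflation factor f >= 1 (default 3).
#' @param within_correlation Target pairwise module correlation rho in
#'   \[0, 1) (default 0.8).
#' @param deg_set_size Planted DEG-like set size (default 200).
#' @param deg_mean_shift Mean shift delta at non-reference stages
#'   (default 2, log2 scale).
#' @param baseline_mean,baseline_sd Gene-level mean location mu0 (default
#'   7) and replicate noise SD sigma0 (default 0.5), log2-like units.
#' @param mean_spread SD of gene-level baseline means around mu0
#'   (default 1).
#' @param seed Integer seed; every run is fully reproducible from it.
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_genes = 4000,
                            stages = c("FR4", "FR8", "IR8", "SR8"),
                            replicates_per_stage = 3,
                            reference_stage = stages[1],
                            tipping_stage = stages[2],
                            dnb_module_size = 60,
                            variance_inflation = 3,
                            within_correlation = 0.8,
                            deg_set_size = 200,
                            deg_mean_shift = 2,
                            baseline_mean = 7,
                            baseline_sd = 0.5,
                            mean_spread = 1,
                            seed = 1L) {
  spec <- list(n_genes = as.integer(n_genes), stages = as.character(stages),
               replicates_per_stage = as.integer(replicates_per_stage),
               reference_stage = reference_stage,
               tipping_stage = tipping_stage,
               dnb_module_size = as.integer(dnb_module_size),
               variance_inflation = variance_inflation,
               within_correlation = within_correlation,
               deg_set_size = as.integer(deg_set_size),
               deg_mean_shift = deg_mean_shift,
               baseline_mean = baseline_mean, baseline_sd = baseline_sd,
               mean_spread = mean_spread, seed = as.integer(seed))
  validate_simulation_spec(spec)
  structure(spec, class = "simulation_spec")
}

validate_simulation_spec <- function(spec) {
  with(spec, {
    if (dnb_module_size + deg_set_size > n_genes) {
      abort("dnb_module_size + deg_set_size must not exceed n_genes")
    }
    if (!reference_stage %in% stages) abort("reference_stage not in stages")
    if (!tipping_stage %in% stages) abort("tipping_stage not in stages")
    if (tipping_stage == reference_stage) {
      abort("tipping_stage must differ from the reference stage")
    }
    if (replicates_per_stage < 2) abort("need >= 2 replicates per stage")
    if (variance_inflation < 1) abort("variance_inflation must be >= 1")
    if (within_correlation < 0 || within_correlation >= 1) {
      abort("within_correlation must lie in [0, 1)")
    }
    if (baseline_sd <= 0) abort("baseline_sd must be > 0")
  })
  invisible(spec)
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec> ", x$n_genes, " genes, ",
      length(x$stages), " stages x ", x$replicates_per_stage,
      " replicates\n", sep = "")
  cat("  module m=", x$dnb_module_size, " at ", x$tipping_stage,
      " (f=", x$variance_inflation, ", rho=", x$within_correlation,
      "), DEG n=", x$deg_set_size, " (delta=", x$deg_mean_shift, ")\n",
      sep = "")
  invisible(x)
}

#' Simulate a staged expression experiment with planted structure
#'
#' @param spec A [simulation_spec()].
#' @return A list with `expr` (an [expression_matrix()] of log-scale
#'   values) and `truth` (class `simulated_truth`: planted `dnb_genes`,
#'   `deg_genes`, `tipping_stage`, all `gene_ids`, and `realized` per-gene
#'   module SD/mean-correlation at the tipping stage).
#' @export
simulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  validate_simulation_spec(spec)
  set.seed(spec$seed)
  S <- length(spec$stages)
  r <- spec$replicates_per_stage
  n <- spec$n_genes
  genes <- sprintf("g%05d", seq_len(n))

  planted <- sample(genes, spec$dnb_module_size + spec$deg_set_size)
  dnb <- sort(planted[seq_len(spec$dnb_module_size)])
  deg <- sort(planted[-seq_len(spec$dnb_module_size)])

  samples <- tibble(
    sample = paste0(rep(spec$stages, each = r), "_r", rep(seq_len(r), S)),
    stage = rep(spec$stages, each = r),
    replicate = rep(seq_len(r), S)
  )
  design <- stage_design(samples, reference = spec$reference_stage,
                         stages = spec$stages)

  mu <- rnorm(n, spec$baseline_mean, spec$mean_spread)
  names(mu) <- genes
  values <- mu + matrix(rnorm(n * S * r, 0, spec$baseline_sd), n, S * r)
  dimnames(values) <- list(genes, samples$sample)

  # planted module: shared factor per tipping-stage sample gives pairwise
  # correlation rho and SD f * sigma0
  tip_cols <- samples$sample[samples$stage == spec$tipping_stage]
  z <- rnorm(r)
  e <- matrix(rnorm(length(dnb) * r), length(dnb), r)
  rho <- spec$within_correlation
  values[dnb, tip_cols] <- mu[dnb] + spec$variance_inflation *
    spec$baseline_sd * (sqrt(rho) * matrix(z, length(dnb), r, byrow = TRUE) +
                          sqrt(1 - rho) * e)

  for (s in setdiff(spec$stages, spec$reference_stage)) {
    cols <- samples$sample[samples$stage == s]
    values[deg, cols] <- values[deg, cols] + spec$deg_mean_shift
  }

  expr <- expression_matrix(values, design)
  mod_vals <- values[dnb, tip_cols, drop = FALSE]
  realized_sd <- row_sds(mod_vals)
  realized_cor <- if (length(dnb) >= 2) {
    cm <- cor(t(mod_vals))
    mean(cm[upper.tri(cm)])
  } else {
    NA_real_
  }
  truth <- structure(
    list(dnb_genes = dnb, deg_genes = deg,
         tipping_stage = spec$tipping_stage, gene_ids = genes,
         realized = list(module_sd = realized_sd,
                         module_mean_cor = realized_cor),
         spec = spec),
    class = "simulated_truth")
  list(expr = expr, truth = truth)
}

#' @export
print.simulated_truth <- function(x, ...) {
  cat("<simulated_truth> ", length(x$dnb_genes), " DNB genes at ",
      x$tipping_stage, "; ", length(x$deg_genes), " DEG genes\n", sep = "")
  invisible(x)
}

#' Simulate a negative-binomial count experiment for the GeTMM path
#'
#' Counts for `n_genes` genes across `n_samples` samples with log-normal
#' expected expression, gene lengths uniform on \[`min_len`, `max_len`\]
#' and negative-binomial noise; sample depths vary log-normally.
#'
#' @param n_genes,n_samples Dimensions.
#' @param dispersion NB dispersion (size = 1/dispersion; default 0.1).
#' @param min_len,max_len Gene length range in bp.
#' @param depth_sd SD of log-normal per-sample depth factors (default 0.3).
#' @param seed Integer seed.
#' @return A [count_matrix()].
#' @export
simulate_counts <- function(n_genes = 500, n_samples = 6, dispersion = 0.1,
                            min_len = 500, max_len = 5000, depth_sd = 0.3,
                            seed = 1L) {
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  lens <- stats::runif(n_genes, min_len, max_len)
  lambda <- exp(rnorm(n_genes, 4, 1.5)) * lens / 1000
  depth <- exp(rnorm(n_samples, 0, depth_sd))
  counts <- vapply(seq_len(n_samples), function(j) {
    stats::rnbinom(n_genes, mu = lambda * depth[j], size = 1 / dispersion)
  }, numeric(n_genes))
  dimnames(counts) <- list(genes, paste0("s", seq_len(n_samples)))
  count_matrix(counts, setNames(lens, genes))
}

#' Simulate a TF-to-target edge list around the planted gene sets
#'
#' Planted edges place DNB genes upstream of DEG genes (each DEG gene
#' receives an edge from a random planted DNB gene with probability
#' `p_dnb_deg`), so the downstream overlay analysis can probe the
#' DNB-upstream-of-DEG configuration; `n_extra_edges` random gene pairs
#' are added as background.
#'
#' @param truth A `simulated_truth`.
#' @param n_extra_edges Number of random background edges (default 200).
#' @param p_dnb_deg Probability a DEG gene gains a DNB parent (default 0.5).
#' @param seed Integer seed.
#' @return An edge tibble (`tf`, `target`, `n_records`).
#' @export
simulate_trn <- function(truth, n_extra_edges = 200, p_dnb_deg = 0.5,
                         seed = 1L) {
  stopifnot(inherits(truth, "simulated_truth"))
  set.seed(seed)
  planted <- NULL
  if (length(truth$dnb_genes) > 0 && length(truth$deg_genes) > 0 &&
      p_dnb_deg > 0) {
    hit <- stats::runif(length(truth$deg_genes)) < p_dnb_deg
    if (any(hit)) {
      planted <- tibble(
        tf = sample(truth$dnb_genes, sum(hit), replace = TRUE),
        target = truth$deg_genes[hit]
      )
    }
  }
  extra <- NULL
  if (n_extra_edges > 0) {
    extra <- tibble(
      tf = sample(truth$gene_ids, n_extra_edges, replace = TRUE),
      target = sample(truth$gene_ids, n_extra_edges, replace = TRUE)
    )
  }
  edges <- bind_rows(planted, extra)
  if (is.null(edges) || nrow(edges) == 0) {
    return(tibble(tf = character(), target = character(),
                  n_records = integer()))
  }
  regulatory_edges(edges)
}

#' Simulate gene-set collections and GO-style annotations
#'
#' Gene sets are sampled from the simulated gene namespace with a
#' configurable sampling-weight `enrichment` for planted DNB genes
#' (1 = no association, so overlap odds ratios are ~1 over seeds). Default
#' set sizes follow the literature-derived functional collections of the
#' cassava storage-root system (SR-related 1925, phytohormone 445,
#' carbohydrate 929, TF 2267, secondary cell growth 1392, kinase 1498),
#' truncated to the simulated gene count. A GO-style gene-to-term map is
#' generated alongside, with `go_enriched_terms` terms favouring DNB genes
#' by `go_enrichment`.
#'
#' @param truth A `simulated_truth`.
#' @param sizes Named integer vector of set sizes.
#' @param enrichment Sampling weight of DNB genes in the functional sets
#'   (default 1 = none).
#' @param n_go_terms Number of GO-style terms (default 30).
#' @param go_term_size Mean term size (default 80).
#' @param go_enriched_terms How many terms favour DNB genes (default 2).
#' @param go_enrichment Sampling weight of DNB genes in those terms
#'   (default 20).
#' @param seed Integer seed.
#' @return A list with `collection` (a `gene_set_collection`) and
#'   `go_annotations` (tibble `gene`, `term`, `name`, `namespace`).
#' @export
simulate_genesets <- function(truth,
                              sizes = c(sr_related = 1925,
                                        phytohormone = 445,
                                        carbohydrate = 929,
                                        tf = 2267,
                                        secondary_cell_growth = 1392,
                                        kinase = 1498),
                              enrichment = 1,
                              n_go_terms = 30, go_term_size = 80,
                              go_enriched_terms = 2, go_enrichment = 20,
                              seed = 1L) {
  stopifnot(inherits(truth, "simulated_truth"))
  set.seed(seed)
  genes <- truth$gene_ids
  n <- length(genes)
  sizes <- pmin(sizes, n)
  if (any(sizes > n)) abort("gene-set sizes exceed the simulated gene count")
  w_dnb <- ifelse(genes %in% truth$dnb_genes, enrichment, 1)
  collection <- lapply(sizes, function(sz) {
    sort(sample(genes, sz, prob = w_dnb))
  })
  names(collection) <- names(sizes)
  collection <- structure(
    collection,
    descriptions = setNames(rep("simulated functional set", length(sizes)),
                            names(sizes)),
    class = "gene_set_collection")

  go <- purrr::map_dfr(seq_len(n_go_terms), function(j) {
    sz <- max(5L, stats::rpois(1, go_term_size))
    w <- if (j <= go_enriched_terms) {
      ifelse(genes %in% truth$dnb_genes, go_enrichment, 1)
    } else {
      rep(1, n)
    }
    tibble(gene = sample(genes, min(sz, n), prob = w),
           term = sprintf("GO:%07d", j),
           name = sprintf("simulated process %d", j),
           namespace = "biological_process")
  })
  list(collection = collection, go_annotations = distinct(go))
}

#' Recovery metrics of a DNB result against planted truth
#'
#' @param result A `dnb_result`.
#' @param truth A `simulated_truth` on the same gene namespace.
#' @return One-row tibble: `stage_correct`, `jaccard`, `precision`,
#'   `recall`, `n_recovered`.
#' @export
recovery_metrics <- function(result, truth) {
  stopifnot(inherits(result, "dnb_result"), inherits(truth, "simulated_truth"))
  rec <- result$dnb_genes
  pl <- truth$dnb_genes
  inter <- length(intersect(rec, pl))
  uni <- length(union(rec, pl))
  tibble(
    stage_correct = identical(result$tipping_stage, truth$tipping_stage),
    jaccard = if (uni == 0) NA_real_ else inter / uni,
    precision = if (length(rec) == 0) NA_real_ else inter / length(rec),
    recall = if (length(pl) == 0) NA_real_ else inter / length(pl),
    n_recovered = length(rec)
  )
}
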