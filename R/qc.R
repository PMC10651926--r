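#' Per-gene, per-stage mean, SD and coefficient of variation
#'
#' SD uses the n-1 denominator over a stage's biological replicates; the
#' coefficient of variation CV = SD/mean is reported as `NA` (and counted)
#' where the stage mean is not positive, since it is undefined at mean 0
#' and uninterpretable for negative means.
#'
#' @param expr An [expression_matrix()] with a design in which every stage
#'   has at least 2 replicates.
#' @return A tibble with columns `gene_id`, `stage`, `mean`, `sd`, `cv`.
#' @export
stage_stats <- function(expr) {
  stopifnot(inherits(expr, "expr_mat"))
  if (is.null(expr$design)) abort("stage_stats needs a stage design")
  reps <- table(expr$design$samples$stage)
  if (any(reps < 2)) {
    abort(paste0("stage(s) with a single replicate: ",
                 paste(names(reps)[reps < 2], collapse = ", ")))
  }
  out <- purrr::map_dfr(expr$design$stages, function(s) {
    m <- stage_values(expr, s)
    mu <- rowMeans(m)
    sdev <- row_sds(m)
    tibble(gene_id = rownames(m), stage = s, mean = unname(mu),
           sd = unname(sdev),
           cv = unname(ifelse(mu > 0, sdev / mu, NA_real_)))
  })
  n_undef <- sum(is.na(out$cv))
  if (n_undef > 0) {
    inform(paste0("CV undefined (non-positive mean) for ", n_undef,
                  " gene x stage combination(s)"))
  }
  out
}

#' Compare per-gene CV distributions between two stages
#'
#' Two-sided Wilcoxon rank-sum test (paired signed-rank optionally) on the
#' per-gene CV values of two stages, with the median difference
#' (stage_b - stage_a) as effect summary.
#'
#' @param stats Output of [stage_stats()].
#' @param stage_a,stage_b Stage labels.
#' @param paired Use the paired signed-rank form? Default `FALSE`.
#' @return A one-row tibble: `stage_a`, `stage_b`, `median_diff`,
#'   `statistic`, `p_value`, `n_genes`.
#' @export
compare_cv <- function(stats, stage_a, stage_b, paired = FALSE) {
  for (s in c(stage_a, stage_b)) {
    if (!s %in% stats$stage) abort(paste0("stage '", s, "' not in `stats`"))
  }
  wide <- stats |>
    select("gene_id", "stage", "cv") |>
    filter(.data$stage %in% c(stage_a, stage_b)) |>
    tidyr::pivot_wider(names_from = "stage", values_from = "cv")
  cva <- wide[[stage_a]]
  cvb <- wide[[stage_b]]
  keep <- is.finite(cva) & is.finite(cvb)
  cva <- cva[keep]; cvb <- cvb[keep]
  if (length(cva) < 10) abort("need >= 10 genes with defined CV in both stages")
  wt <- suppressWarnings(
    wilcox.test(cvb, cva, paired = paired, exact = FALSE)
  )
  tibble(stage_a = stage_a, stage_b = stage_b,
         median_diff = median(cvb) - median(cva),
         statistic = unname(wt$statistic), p_value = wt$p.value,
         n_genes = length(cva))
}

#' PCA of samples on gene-centered expression
#'
#' Samples are the observations and genes the variables; each gene is
#' centered across samples. For reproducibility the sign of each component
#' is fixed so that the gene with the largest absolute loading has a
#' positive loading.
#'
#' @param expr An [expression_matrix()] with >= 3 samples.
#' @param n_pc Number of components to keep (default: all).
#' @return An object of class `sample_pca`: list with `scores` (tibble of
#'   sample, stage, PC columns) and `var_explained` (numeric, sums to 1
#'   over all components).
#' @export
pca_samples <- function(expr, n_pc = NULL) {
  stopifnot(inherits(expr, "expr_mat"))
  m <- expr$values
  if (ncol(m) < 3) abort("PCA needs >= 3 samples")
  if (all(row_sds(m) == 0)) abort("constant matrix: PCA is undefined")
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  # fix sign: largest-|loading| gene positive per component
  for (j in seq_len(ncol(pc$rotation))) {
    i <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  k <- min(n_pc %||% ncol(pc$x), ncol(pc$x))
  scores <- as_tibble(pc$x[, seq_len(k), drop = FALSE])
  scores <- bind_cols_sample_info(scores, colnames(m), expr$design)
  structure(list(scores = scores, var_explained = ve),
            class = "sample_pca")
}

bind_cols_sample_info <- function(scores, sample_ids, design) {
  info <- tibble(sample = sample_ids)
  if (!is.null(design)) info <- left_join(info, design$samples, by = "sample")
  dplyr::bind_cols(info, scores)
}

#' @export
print.sample_pca <- function(x, ...) {
  cat("<sample_pca> ", nrow(x$scores), " samples; PC1 ",
      sprintf("%.1f%%", 100 * x$var_explained[1]), ", PC2 ",
      sprintf("%.1f%%", 100 * x$var_explained[2]), " of variance\n", sep = "")
  invisible(x)
}

#' @export
tidy.sample_pca <- function(x, ...) x$scores

#' @export
glance.sample_pca <- function(x, ...) {
  tibble(n_samples = nrow(x$scores),
         pc1_var = x$var_explained[1],
         pc2_var = x$var_explained[2])
}

#' @export
autoplot.sample_pca <- function(object, ...) {
  p <- ggplot2::ggplot(object$scores,
                       ggplot2::aes(x = .data$PC1, y = .data$PC2))
  if ("stage" %in% names(object$scores)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data$stage), size = 3)
  } else {
    p <- p + ggplot2::geom_point(size = 3)
  }
  p +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_explained[2])
    ) +
    ggplot2::theme_minimal()
}

#' Agglomerative clustering of samples
#'
#' Euclidean distance between sample expression profiles with complete
#' linkage (the default of the heatmap tooling this mirrors); other
#' linkages via `linkage`.
#'
#' @param expr An [expression_matrix()] with >= 2 samples.
#' @param k Optional number of flat clusters to cut.
#' @param linkage Linkage method for [stats::hclust()] (default "complete").
#' @return An object of class `sample_clustering`: list with the `hclust`
#'   tree and, when `k` is given, a `labels` tibble (sample, cluster).
#' @export
cluster_samples <- function(expr, k = NULL, linkage = "complete") {
  stopifnot(inherits(expr, "expr_mat"))
  if (ncol(expr$values) < 2) abort("need >= 2 samples")
  d <- dist(t(expr$values), method = "euclidean")
  tree <- hclust(d, method = linkage)
  labels <- NULL
  if (!is.null(k)) {
    cl <- cutree(tree, k = k)
    labels <- tibble(sample = names(cl), cluster = as.integer(cl))
  }
  structure(list(tree = tree, labels = labels, k = k),
            class = "sample_clustering")
}

#' @export
print.sample_clustering <- function(x, ...) {
  cat("<sample_clustering> ", length(x$tree$labels), " samples",
      if (!is.null(x$k)) paste0(", cut at k = ", x$k), "\n", sep = "")
  invisible(x)
}

#' Export a sample dendrogram as Newick
#' @param clustering A [cluster_samples()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(clustering, path) {
  stopifnot(inherits(clustering, "sample_clustering"))
  phy <- ape::as.phylo(clustering$tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
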