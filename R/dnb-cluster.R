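#' Cluster a stage's candidate genes by absolute correlation
#'
#' Agglomerative (average-linkage) clustering of the stage's candidate
#' genes using the distance `1 - |PCC|` over that stage's replicate
#' columns, cut into exactly `k` clusters. A Euclidean mode is available
#' for comparison. Following the published protocol for the cassava
#' system, the default cut is K = 80.
#'
#' @param expr An [expression_matrix()] with a design.
#' @param candidates Output of [select_candidates()] (or any tibble with
#'   `gene_id`, `stage`, `selected`).
#' @param stage Stage whose candidates to cluster.
#' @param k Number of clusters (default 80).
#' @param distance `"abs_pcc"` (default) or `"euclidean"`.
#' @param allow_small_k If the number of candidates is below `k`, reduce
#'   `k` to the candidate count instead of erroring (default `FALSE`).
#' @return A tibble with columns `gene_id`, `stage`, `cluster` (indices
#'   1..k, contiguous); the tree is kept in `attr(, "tree")` and the cut
#'   actually used in `attr(, "k")`.
#' @export
cluster_genes <- function(expr, candidates, stage, k = 80,
                          distance = c("abs_pcc", "euclidean"),
                          allow_small_k = FALSE) {
  stopifnot(inherits(expr, "expr_mat"))
  distance <- match.arg(distance)
  genes <- candidates$gene_id[candidates$stage == stage & candidates$selected]
  n <- length(genes)
  if (k < 2) abort("k must be >= 2")
  if (n < k) {
    if (!allow_small_k) {
      abort(paste0(n, " candidate gene(s) at stage '", stage, "' but k = ", k,
                   "; use a smaller k (or allow_small_k = TRUE)"))
    }
    k <- n
  }
  if (n == 0) abort(paste0("no candidate genes at stage '", stage, "'"))
  m <- stage_values(expr, stage)[genes, , drop = FALSE]
  if (n == 1) {
    out <- tibble(gene_id = genes, stage = stage, cluster = 1L)
    attr(out, "k") <- 1L
    return(out)
  }
  d <- if (distance == "abs_pcc") {
    ac <- abs_cor_matrix(m)
    r <- ac$r
    # zero-variance genes have undefined correlation; place them maximally far
    r[is.na(r)] <- 0
    diag(r) <- 1
    stats::as.dist(1 - r)
  } else {
    dist(m, method = "euclidean")
  }
  tree <- hclust(d, method = "average")
  cl <- cutree(tree, k = k)
  out <- tibble(gene_id = genes, stage = stage, cluster = as.integer(cl))
  attr(out, "tree") <- tree
  attr(out, "k") <- k
  out
}

#' Per-cluster DNB statistics and composite index
#'
#' Using only the focal stage's replicate columns: `SD_in` is the mean over
#' member genes of the per-gene replicate SD; `|PCC_in|` the mean absolute
#' Pearson correlation over all unordered member pairs (0 for singleton
#' clusters, which cannot evidence within-group coherence); `|PCC_out|` the
#' mean absolute correlation over all (member, background non-member)
#' pairs; and the composite index
#' `CI = SD_in * |PCC_in| / |PCC_out|`.
#' Genes with zero replicate variance have undefined correlations: their
#' pairs are skipped (and counted) while their zero SDs still enter
#' `SD_in`. A cluster with `|PCC_out| = 0` gets an infinite CI, flagged.
#'
#' @param expr An [expression_matrix()] with a design.
#' @param clustering Output of [cluster_genes()] for one stage.
#' @param background `"candidates"` (default): the out-group is the other
#'   clustered candidate genes at this stage; `"all_genes"`: all other
#'   genes in the matrix.
#' @return A tibble with columns `stage`, `cluster`, `n_genes`, `sd_in`,
#'   `pcc_in_abs`, `pcc_out_abs`, `ci`, `ci_infinite`; the number of pairs
#'   skipped for zero variance is in `attr(, "n_zero_var_genes")`.
#' @export
dnb_cluster_stats <- function(expr, clustering,
                              background = c("candidates", "all_genes")) {
  stopifnot(inherits(expr, "expr_mat"))
  background <- match.arg(background)
  stage <- unique(clustering$stage)
  if (length(stage) != 1) abort("clustering must refer to exactly one stage")
  member_genes <- clustering$gene_id
  bg_genes <- if (background == "candidates") {
    member_genes
  } else {
    gene_ids(expr)
  }
  m <- stage_values(expr, stage)[union(member_genes, bg_genes), , drop = FALSE]
  sds <- row_sds(m)
  ac <- abs_cor_matrix(m)
  r <- ac$r

  ks <- sort(unique(clustering$cluster))
  out <- purrr::map_dfr(ks, function(kk) {
    members <- clustering$gene_id[clustering$cluster == kk]
    outsiders <- setdiff(bg_genes, members)
    sd_in <- mean(sds[members])
    pcc_in <- if (length(members) < 2) 0 else {
      rr <- r[members, members, drop = FALSE]
      vals <- rr[upper.tri(rr)]
      if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
    }
    pcc_out <- if (length(outsiders) == 0) 0 else {
      vals <- r[members, outsiders, drop = FALSE]
      if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
    }
    ci_inf <- pcc_out == 0 && sd_in * pcc_in > 0
    ci <- if (pcc_out > 0) sd_in * pcc_in / pcc_out else if (ci_inf) Inf else 0
    tibble(stage = stage, cluster = kk, n_genes = length(members),
           sd_in = sd_in, pcc_in_abs = pcc_in, pcc_out_abs = pcc_out,
           ci = ci, ci_infinite = ci_inf)
  })
  if (any(out$ci_infinite)) {
    warn(paste0(sum(out$ci_infinite), " cluster(s) with |PCC_out| = 0: ",
                "CI reported as +Inf"))
  }
  attr(out, "n_zero_var_genes") <- ac$n_zero_var
  attr(out, "background") <- background
  out
}

#' Composite index from its three components
#'
#' `CI = SD_in * |PCC_in| / |PCC_out|`: high replicate variability and
#' tight mutual correlation inside the group, weak correlation with the
#' rest of the transcriptome.
#'
#' @param sd_in Mean within-cluster replicate SD (>= 0).
#' @param pcc_in_abs Mean absolute within-cluster correlation in \[0, 1\].
#' @param pcc_out_abs Mean absolute member-outsider correlation in \[0, 1\].
#' @return Numeric CI (Inf when `pcc_out_abs` is 0 and the numerator is
#'   positive, 0 when the numerator is 0).
#' @export
composite_index <- function(sd_in, pcc_in_abs, pcc_out_abs) {
  num <- sd_in * pcc_in_abs
  ifelse(pcc_out_abs > 0, num / pcc_out_abs, ifelse(num > 0, Inf, 0))
}
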