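#' Overlay DNB and DEG gene sets on a regulatory edge list
#'
#' Builds the annotated TF-to-target network relating a DNB gene set to a
#' set of differentially expressed genes. Two documented inclusion rules:
#' `dnb_anchored` (default) keeps edges with at least one endpoint in the
#' DNB set and both endpoints in the DNB/DEG union (DNBs plus first-order
#' neighbouring DEGs); `induced` keeps every edge with both endpoints in
#' the union. Isolated genes are dropped; each retained node is labelled
#' `dnb_only`, `overlap` (in both sets) or `deg_only`, and flagged as a TF
#' if it appears on the source side of any input edge (or in `tf_ids`).
#'
#' @param edges Edge tibble with columns `tf`, `target` (see
#'   [regulatory_edges()]).
#' @param dnb Character vector of DNB gene ids.
#' @param deg Character vector of DEG-derived gene ids.
#' @param mode `"dnb_anchored"` (default) or `"induced"`.
#' @param tf_ids Optional additional TF ids.
#' @return An object of class `annotated_network`: list of `nodes` (tibble
#'   with `gene_id`, `group`, `is_tf`) and `edges`.
#' @export
build_network <- function(edges, dnb, deg,
                          mode = c("dnb_anchored", "induced"),
                          tf_ids = NULL) {
  mode <- match.arg(mode)
  if (length(dnb) == 0 || length(deg) == 0) {
    abort("both the DNB and DEG gene sets must be non-empty")
  }
  edges <- as_tibble(edges)
  u <- union(dnb, deg)
  keep <- if (mode == "dnb_anchored") {
    (edges$tf %in% dnb | edges$target %in% dnb) &
      edges$tf %in% u & edges$target %in% u
  } else {
    edges$tf %in% u & edges$target %in% u
  }
  kept <- edges[keep, , drop = FALSE]
  if (nrow(kept) == 0) {
    warn("no edge links the supplied gene sets: empty network")
  }
  node_ids <- union(kept$tf, kept$target)
  nodes <- tibble(
    gene_id = node_ids,
    group = dplyr::case_when(
      node_ids %in% dnb & node_ids %in% deg ~ "overlap",
      node_ids %in% dnb ~ "dnb_only",
      TRUE ~ "deg_only"
    ),
    is_tf = node_ids %in% union(edges$tf, tf_ids %||% character(0))
  )
  structure(list(nodes = nodes, edges = kept, mode = mode),
            class = "annotated_network")
}

#' @export
print.annotated_network <- function(x, ...) {
  cat("<annotated_network> ", nrow(x$nodes), " nodes, ", nrow(x$edges),
      " edges (", x$mode, ")\n", sep = "")
  if (nrow(x$nodes) > 0) {
    print(count(x$nodes, .data$group))
  }
  invisible(x)
}

#' @export
tidy.annotated_network <- function(x, ...) x$nodes

#' @export
glance.annotated_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_dnb_only = sum(x$nodes$group == "dnb_only"),
         n_overlap = sum(x$nodes$group == "overlap"),
         n_deg_only = sum(x$nodes$group == "deg_only"),
         mode = x$mode)
}

#' Mean-rank percentile of a set of values
#'
#' `pct = 100 * (rank_avg - 0.5) / n`, with ties sharing the average rank;
#' bounded in (0, 100) and invariant to monotone transforms. Non-finite
#' values are excluded (returned as `NA`) and counted.
#'
#' @param values Numeric vector, optionally named.
#' @return Numeric vector of percentiles, same length and names; the
#'   number of excluded non-finite values is in `attr(, "n_excluded")`.
#' @export
#' @examples
#' percentile_rank(c(1, 2, 3, 4))
percentile_rank <- function(values) {
  ok <- is.finite(values)
  out <- rep(NA_real_, length(values))
  names(out) <- names(values)
  if (any(ok)) {
    r <- rank(values[ok], ties.method = "average")
    out[ok] <- 100 * (r - 0.5) / sum(ok)
  }
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Expression-ratio and SD-ratio signatures relative to a reference stage
#'
#' For every gene, the ratio of replicate means and of replicate SDs
#' between two stages (numerator over denominator stage), plus the
#' percentile rank of each ratio over all genes in the matrix. This is the
#' contrast that separates DNB-like genes (SD ratio high, expression ratio
#' mid-range) from DEG-like genes (expression ratio high, SD ratio
#' mid-range).
#'
#' @param expr An [expression_matrix()] with a design.
#' @param stage_num,stage_den Stage labels for numerator and denominator.
#' @param scale `"linear"` (default): ratios of means/SDs of the values as
#'   stored; `"log"`: values are exponentiated from log2 before the means.
#' @return A tibble with columns `gene_id`, `expr_ratio`, `sd_ratio`,
#'   `expr_ratio_pct`, `sd_ratio_pct`. Zero denominators yield `NA`
#'   (flagged via `attr(, "n_zero_denom")`).
#' @export
signature_ratios <- function(expr, stage_num, stage_den,
                             scale = c("linear", "log")) {
  stopifnot(inherits(expr, "expr_mat"))
  scale <- match.arg(scale)
  a <- stage_values(expr, stage_num)
  b <- stage_values(expr, stage_den)
  if (scale == "log") {
    a <- 2^a
    b <- 2^b
  }
  mean_num <- rowMeans(a); mean_den <- rowMeans(b)
  sd_num <- row_sds(a); sd_den <- row_sds(b)
  expr_ratio <- ifelse(mean_den != 0, mean_num / mean_den, NA_real_)
  sd_ratio <- ifelse(sd_den > 0, sd_num / sd_den, NA_real_)
  n_zero <- sum(mean_den == 0) + sum(sd_den == 0)
  out <- tibble(
    gene_id = rownames(a),
    expr_ratio = unname(expr_ratio),
    sd_ratio = unname(sd_ratio),
    expr_ratio_pct = as.numeric(percentile_rank(expr_ratio)),
    sd_ratio_pct = as.numeric(percentile_rank(sd_ratio))
  )
  attr(out, "n_zero_denom") <- n_zero
  out
}

#' Annotate network nodes with percentile-ranked stage ratios
#'
#' Computes each node's expression ratio (ratio of replicate means) and SD
#' ratio between two stages, and converts both to percentile ranks over
#' the network's nodes. Nodes absent from the matrix keep `NA` attributes
#' and are counted.
#'
#' @param net An [build_network()] result.
#' @param expr An [expression_matrix()] with a design.
#' @param stage_num,stage_den Stage labels (e.g. the tipping stage and the
#'   reference stage).
#' @param scale See [signature_ratios()].
#' @return The network with node columns `expr_ratio`, `sd_ratio`,
#'   `expr_ratio_pct`, `sd_ratio_pct` added.
#' @export
annotate_ratios <- function(net, expr, stage_num, stage_den,
                            scale = c("linear", "log")) {
  stopifnot(inherits(net, "annotated_network"))
  scale <- match.arg(scale)
  sig <- signature_ratios(expr, stage_num, stage_den, scale = scale)
  nodes <- left_join(net$nodes,
                     select(sig, "gene_id", "expr_ratio", "sd_ratio"),
                     by = "gene_id")
  n_absent <- sum(!nodes$gene_id %in% sig$gene_id)
  if (n_absent > 0) {
    inform(paste0(n_absent, " node(s) absent from the expression matrix"))
  }
  nodes$expr_ratio_pct <- as.numeric(percentile_rank(nodes$expr_ratio))
  nodes$sd_ratio_pct <- as.numeric(percentile_rank(nodes$sd_ratio))
  net$nodes <- nodes
  net
}

#' Export an annotated network
#'
#' Formats: `sif` (lines `tf regulates target`), `graphml` (with all node
#' attributes, via igraph) and `tsv` (lossless node/edge table pair,
#' re-readable with [read_network_tsv()]).
#'
#' @param net An [build_network()] result.
#' @param path Output path (for `tsv`, the prefix: writes
#'   `<path>_nodes.tsv` and `<path>_edges.tsv`).
#' @param format `"sif"`, `"graphml"` or `"tsv"`.
#' @return The path(s) written, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "tsv")) {
  stopifnot(inherits(net, "annotated_network"))
  format <- rlang::arg_match(format)
  if (format == "sif") {
    writeLines(paste(net$edges$tf, "regulates", net$edges$target), path)
    return(invisible(path))
  }
  if (format == "graphml") {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(path))
  }
  paths <- paste0(path, c("_nodes.tsv", "_edges.tsv"))
  write_tsv_full(net$nodes, paths[1])
  write_tsv_full(net$edges, paths[2])
  invisible(paths)
}

#' @rdname export_network
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "annotated_network"))
  igraph::graph_from_data_frame(
    as.data.frame(net$edges),
    directed = TRUE,
    vertices = as.data.frame(net$nodes)
  )
}

#' Re-import a network exported as TSV
#' @param path The prefix used in [export_network()] with `format = "tsv"`.
#' @return An `annotated_network`.
#' @export
read_network_tsv <- function(path) {
  nodes <- read_tsv_strict(paste0(path, "_nodes.tsv"))
  edges <- read_tsv_strict(paste0(path, "_edges.tsv"))
  nodes$gene_id <- as.character(nodes$gene_id)
  edges$tf <- as.character(edges$tf)
  edges$target <- as.character(edges$target)
  structure(list(nodes = nodes, edges = edges, mode = "imported"),
            class = "annotated_network")
}
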