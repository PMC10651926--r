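#' Collapse a probe-level matrix to one representative probe per gene
#'
#' Keeps only annotation records with a bidirectional BLAST hit, E-value at
#' most `evalue_max` and identity at least `identity_min` (defaults 1e-10
#' and 95). When several probes survive for a gene, the representative is
#' chosen lexicographically: (1) smallest E-value, (2) largest identity
#' percentage, (3) smallest average replicate SD of the probe's expression,
#' and finally (4) smallest probe id, so the choice is deterministic.
#'
#' @param expr An [expression_matrix()] keyed by probe ids.
#' @param annotation A [probe_annotation()] table.
#' @param evalue_max Maximum E-value (default `1e-10`).
#' @param identity_min Minimum identity percentage (default `95`).
#' @param sd_scope `"per_stage"` (default) computes, for each probe, the SD
#'   over replicates within each stage and averages over stages;
#'   `"global"` uses one SD over all samples.
#' @return An [expression_matrix()] keyed by gene ids. The probe chosen for
#'   each gene is recorded in `attr(, "probe_map")`; probes annotated but
#'   absent from the matrix trigger a warning, and the number of genes
#'   dropped for lack of a surviving probe is reported in
#'   `attr(, "n_genes_dropped")`.
#' @export
collapse_probes <- function(expr, annotation, evalue_max = 1e-10,
                            identity_min = 95,
                            sd_scope = c("per_stage", "global")) {
  stopifnot(inherits(expr, "expr_mat"))
  sd_scope <- match.arg(sd_scope)
  ann <- probe_annotation(annotation)

  n_all_genes <- length(unique(ann$gene_id))
  ann <- filter(ann,
                .data$bidirectional,
                .data$evalue <= evalue_max,
                .data$identity_pct >= identity_min)

  absent <- setdiff(unique(ann$probe_id), rownames(expr$values))
  if (length(absent) > 0) {
    warn(paste0(length(absent), " annotated probe(s) absent from the matrix, ",
                "e.g. ", paste(head(absent, 3), collapse = ", ")))
    ann <- filter(ann, !.data$probe_id %in% absent)
  }

  multi <- ann |>
    distinct(.data$probe_id, .data$gene_id) |>
    count(.data$probe_id) |>
    filter(n > 1)
  if (nrow(multi) > 0) {
    inform(paste0(nrow(multi), " probe(s) hit multiple genes; each (probe, ",
                  "gene) pair is kept and representatives are chosen per gene"))
  }

  probe_sd <- avg_probe_sd(expr, sd_scope)
  ann$avg_sd <- probe_sd[ann$probe_id]

  chosen <- ann |>
    group_by(.data$gene_id) |>
    arrange(.data$evalue, dplyr::desc(.data$identity_pct), .data$avg_sd,
            .data$probe_id, .by_group = TRUE) |>
    slice(1) |>
    ungroup()

  n_dropped <- n_all_genes - nrow(chosen)
  inform(paste0(nrow(chosen), " genes kept; ", n_dropped,
                " gene(s) had no surviving probe"))

  # preserve the probe-level row order of the representatives
  chosen <- chosen[order(match(chosen$probe_id, rownames(expr$values)),
                         chosen$gene_id), ]
  values <- expr$values[chosen$probe_id, , drop = FALSE]
  rownames(values) <- chosen$gene_id
  out <- expression_matrix(values, expr$design)
  attr(out, "probe_map") <- select(chosen, gene_id = "gene_id",
                                   probe_id = "probe_id", evalue = "evalue",
                                   identity_pct = "identity_pct",
                                   avg_sd = "avg_sd")
  attr(out, "n_genes_dropped") <- n_dropped
  out
}

avg_probe_sd <- function(expr, sd_scope) {
  m <- expr$values
  if (sd_scope == "global" || is.null(expr$design)) {
    out <- apply(m, 1, sd)
  } else {
    per_stage <- vapply(expr$design$stages, function(s) {
      row_sds(stage_values(expr, s))
    }, numeric(nrow(m)))
    out <- rowMeans(matrix(per_stage, nrow = nrow(m)))
  }
  setNames(out, rownames(m))
}
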