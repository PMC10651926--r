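#' Pick the representative cluster per stage and the tipping stage
#'
#' The representative cluster of each stage is the one maximizing the
#' composite index (CI operationalizes the three joint DNB criteria —
#' highest SD_in and |PCC_in|, lowest |PCC_out| — as the only total order
#' consistent with its definition; the raw per-cluster statistics are kept
#' so the stricter joint rule can be audited). The tipping stage is the
#' stage whose representative CI is maximal; its cluster members are the
#' DNB gene set. Ties are broken toward the earlier stage in design order,
#' then the lower cluster index, and logged.
#'
#' @param stats Row-bound [dnb_cluster_stats()] tibbles over stages.
#' @param assignments Row-bound [cluster_genes()] tibbles over the same
#'   stages (columns `gene_id`, `stage`, `cluster`).
#' @param stage_order Optional stage ordering (default: order of first
#'   appearance in `stats`).
#' @return An object of class `dnb_result`: list with `trajectory` (one row
#'   per stage: the representative cluster and its statistics),
#'   `cluster_stats` (all clusters), `tipping_stage`, `dnb_genes`,
#'   `no_signal` flag.
#' @export
select_dnb <- function(stats, assignments, stage_order = NULL) {
  if (nrow(stats) == 0) abort("no cluster statistics supplied")
  stage_order <- stage_order %||% unique(stats$stage)
  stats <- mutate(stats,
                  .stage_idx = match(.data$stage, stage_order))
  if (any(is.na(stats$.stage_idx))) abort("stage missing from `stage_order`")

  trajectory <- stats |>
    group_by(.data$stage) |>
    arrange(dplyr::desc(.data$ci), .data$cluster, .by_group = TRUE) |>
    mutate(.tied = sum(.data$ci == max(.data$ci)) > 1) |>
    slice(1) |>
    ungroup() |>
    arrange(.data$.stage_idx)
  if (any(trajectory$.tied)) {
    inform(paste0("CI tie within stage(s) ",
                  paste(trajectory$stage[trajectory$.tied], collapse = ", "),
                  "; lowest cluster index kept"))
  }

  no_signal <- all(trajectory$ci == 0)
  if (no_signal) {
    inform("all representative CIs are zero: no transition signal")
    result <- list(trajectory = select(trajectory, -".stage_idx", -".tied"),
                   cluster_stats = select(stats, -".stage_idx"),
                   tipping_stage = NA_character_,
                   dnb_genes = character(0),
                   no_signal = TRUE)
    return(structure(result, class = "dnb_result"))
  }

  best <- trajectory |>
    arrange(dplyr::desc(.data$ci), .data$.stage_idx) |>
    slice(1)
  if (sum(trajectory$ci == best$ci) > 1) {
    inform("CI tie across stages; earliest stage in design order kept")
  }
  tipping <- best$stage
  dnb_genes <- assignments$gene_id[assignments$stage == tipping &
                                     assignments$cluster == best$cluster]
  structure(
    list(trajectory = select(trajectory, -".stage_idx", -".tied"),
         cluster_stats = select(stats, -".stage_idx"),
         tipping_stage = tipping,
         dnb_genes = dnb_genes,
         no_signal = FALSE),
    class = "dnb_result"
  )
}

#' @export
print.dnb_result <- function(x, ...) {
  cat("<dnb_result>\n")
  if (x$no_signal) {
    cat("  no transition signal (all representative CIs are zero)\n")
  } else {
    cat("  tipping stage: ", x$tipping_stage, "\n", sep = "")
    cat("  DNB genes: ", length(x$dnb_genes), "\n", sep = "")
  }
  cat("  CI trajectory: ",
      paste(sprintf("%s=%.3g", x$trajectory$stage, x$trajectory$ci),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @describeIn select_dnb Tidy per-stage trajectory of the representative
#'   clusters.
#' @param x,object A `dnb_result`.
#' @param ... Unused.
#' @export
tidy.dnb_result <- function(x, ...) x$trajectory

#' @describeIn select_dnb One-row summary of the fit.
#' @export
glance.dnb_result <- function(x, ...) {
  tibble(tipping_stage = x$tipping_stage,
         n_dnb_genes = length(x$dnb_genes),
         max_ci = if (nrow(x$trajectory)) max(x$trajectory$ci) else NA_real_,
         no_signal = x$no_signal)
}

#' @describeIn select_dnb CI trajectory plot across stages.
#' @export
autoplot.dnb_result <- function(object, ...) {
  tr <- object$trajectory
  tr$stage <- factor(tr$stage, levels = tr$stage)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$stage, y = .data$ci, group = 1)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 3, ggplot2::aes(
      colour = .data$stage == object$tipping_stage)) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#D55E00",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = NULL, y = "Composite index (CI)") +
    ggplot2::theme_minimal()
}

#' Run the full DNB stage-detection analysis
#'
#' Chains [select_candidates()], per-stage [cluster_genes()],
#' [dnb_cluster_stats()] and [select_dnb()]. A non-reference stage
#' contributes clusters only if it has at least `min_candidates` selected
#' genes; when a stage has fewer candidates than `k`, the cut is reduced
#' to the candidate count (logged). If no stage yields a cluster the
#' result carries the `no_signal` flag.
#'
#' @param expr An [expression_matrix()] with a design.
#' @param config A [selection_config()].
#' @param k Number of gene clusters per stage (default 80).
#' @param background Out-group for `|PCC_out|`: `"candidates"` (default)
#'   or `"all_genes"`.
#' @param distance Gene-clustering distance (see [cluster_genes()]).
#' @param min_candidates Minimum selected genes for a stage to be scored
#'   (default 2).
#' @return A `dnb_result`; the candidate table is attached as
#'   `attr(, "candidates")` and cluster assignments as
#'   `attr(, "assignments")`.
#' @export
dnb_analysis <- function(expr, config = selection_config(), k = 80,
                         background = c("candidates", "all_genes"),
                         distance = c("abs_pcc", "euclidean"),
                         min_candidates = 2) {
  background <- match.arg(background)
  distance <- match.arg(distance)
  candidates <- select_candidates(expr, config)
  stages <- nonreference_stages(expr$design)

  per_stage <- purrr::map(stages, function(s) {
    n <- sum(candidates$selected[candidates$stage == s])
    if (n < min_candidates) {
      inform(paste0("stage '", s, "': ", n,
                    " candidate(s); skipped (min_candidates = ",
                    min_candidates, ")"))
      return(NULL)
    }
    cl <- cluster_genes(expr, candidates, s, k = k, distance = distance,
                        allow_small_k = TRUE)
    st <- dnb_cluster_stats(expr, cl, background = background)
    list(assignment = cl, stats = st)
  })
  per_stage <- purrr::compact(per_stage)

  if (length(per_stage) == 0) {
    inform("no stage had enough candidate genes: no transition signal")
    result <- structure(
      list(trajectory = tibble(stage = character(), cluster = integer(),
                               n_genes = integer(), sd_in = numeric(),
                               pcc_in_abs = numeric(), pcc_out_abs = numeric(),
                               ci = numeric(), ci_infinite = logical()),
           cluster_stats = NULL,
           tipping_stage = NA_character_,
           dnb_genes = character(0),
           no_signal = TRUE),
      class = "dnb_result")
  } else {
    stats <- bind_rows(purrr::map(per_stage, "stats"))
    assignments <- bind_rows(purrr::map(per_stage, "assignment"))
    result <- select_dnb(stats, assignments, stage_order = stages)
    attr(result, "assignments") <- assignments
  }
  attr(result, "candidates") <- candidates
  result
}
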