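#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, clipped to 1 and mapped back to
#' input order (computed via [stats::p.adjust()]).
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04))
benjamini_hochberg <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must be finite and within [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Configuration for per-stage candidate selection
#'
#' Candidate genes at each non-reference stage are those with a significant
#' change in replicate-level expression variability (q-value at or below
#' the stage's FDR threshold) and a fold-change of replicate SD relative to
#' the reference stage of at least `fc_sd_min`. The default FDR thresholds
#' are the stage-wise values used for the cassava storage-root system
#' (0.72, 0.20, 0.25 for the three non-reference stages in design order)
#' and the default SD fold-change cutoff is 2.
#'
#' @param fdr_thresholds Named numeric vector (stage -> threshold in (0, 1])
#'   or unnamed vector matched positionally to the non-reference stages. The
#'   default `c(0.72, 0.20, 0.25)` requires exactly three non-reference
#'   stages; supply explicit values otherwise.
#' @param fc_sd_min Minimum SD fold-change (default 2).
#' @param test_kind Per-gene test of the stage's replicates against the
#'   reference stage's replicates: `"levene"` (default; Student t-test on
#'   absolute deviations from the replicate mean, targeting variability),
#'   `"student"` / `"welch"` (t-tests of means), or `"var_f"` (one-sided
#'   variance-ratio F test).
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(fdr_thresholds = c(0.72, 0.20, 0.25),
                             fc_sd_min = 2,
                             test_kind = c("levene", "student", "welch", "var_f")) {
  test_kind <- match.arg(test_kind)
  if (any(fdr_thresholds <= 0 | fdr_thresholds > 1)) {
    abort("FDR thresholds must lie in (0, 1]")
  }
  if (!is.numeric(fc_sd_min) || fc_sd_min <= 0) {
    abort("fc_sd_min must be > 0")
  }
  structure(list(fdr_thresholds = fdr_thresholds, fc_sd_min = fc_sd_min,
                 test_kind = test_kind),
            class = "selection_config")
}

#' @export
print.selection_config <- function(x, ...) {
  thr <- if (is.null(names(x$fdr_thresholds))) {
    paste(x$fdr_thresholds, collapse = "/")
  } else {
    paste(names(x$fdr_thresholds), x$fdr_thresholds, sep = "=", collapse = ", ")
  }
  cat("<selection_config> test ", x$test_kind, "; FDR ", thr,
      "; FC_SD >= ", x$fc_sd_min, "\n", sep = "")
  invisible(x)
}

resolve_thresholds <- function(config, design) {
  stages <- nonreference_stages(design)
  thr <- config$fdr_thresholds
  if (!is.null(names(thr)) && any(nzchar(names(thr)))) {
    missing_thr <- setdiff(stages, names(thr))
    if (length(missing_thr) > 0) {
      abort(paste0("no FDR threshold for stage(s): ",
                   paste(missing_thr, collapse = ", ")))
    }
    thr[stages]
  } else {
    if (length(thr) == 1) return(setNames(rep(thr, length(stages)), stages))
    if (length(thr) != length(stages)) {
      abort(paste0("got ", length(thr), " FDR thresholds for ",
                   length(stages), " non-reference stages; supply a named ",
                   "or matching-length vector"))
    }
    setNames(thr, stages)
  }
}

#' Select DNB candidate genes per stage
#'
#' For every non-reference stage, each gene's replicates are tested against
#' the reference stage's replicates (test per `config$test_kind`), p-values
#' are BH-adjusted across genes within the stage, and the fold-change of
#' replicate SD `fc_sd = SD_stage / SD_reference` is computed. A gene is
#' selected at a stage iff its q-value is at or below the stage threshold
#' and `fc_sd >= fc_sd_min`. Genes with zero reference-stage SD have an
#' undefined fold-change; they are excluded and counted.
#'
#' @param expr An [expression_matrix()] with a design.
#' @param config A [selection_config()].
#' @return A tibble with columns `gene_id`, `stage`, `p_value`, `q_value`,
#'   `fc_sd`, `selected`; the per-stage count of excluded zero-SD-reference
#'   genes is in `attr(, "n_sd_ref_zero")`.
#' @export
select_candidates <- function(expr, config = selection_config()) {
  stopifnot(inherits(expr, "expr_mat"), inherits(config, "selection_config"))
  if (is.null(expr$design)) abort("select_candidates needs a stage design")
  design <- expr$design
  thr <- resolve_thresholds(config, design)
  ref <- stage_values(expr, design$reference_stage)
  sd_ref <- row_sds(ref)
  n_zero <- integer(0)

  out <- purrr::map_dfr(nonreference_stages(design), function(s) {
    m <- stage_values(expr, s)
    test <- switch(config$test_kind,
      student = row_t_test(m, ref, pooled = TRUE),
      welch = row_t_test(m, ref, pooled = FALSE),
      levene = row_levene_test(m, ref),
      var_f = row_var_f_test(m, ref)
    )
    ok <- sd_ref > 0
    n_zero[[s]] <<- sum(!ok)
    fc <- ifelse(ok, row_sds(m) / sd_ref, NA_real_)
    p <- test$p_value
    p[!is.finite(p)] <- 1
    q <- benjamini_hochberg(p)
    tibble(gene_id = rownames(m), stage = s, p_value = unname(p),
           q_value = unname(q), fc_sd = unname(fc),
           selected = unname(ok & q <= thr[[s]] & fc >= config$fc_sd_min))
  })
  attr(out, "n_sd_ref_zero") <- n_zero
  attr(out, "thresholds") <- thr
  out
}
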