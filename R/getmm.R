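#' TMM normalization factors
#'
#' Standard trimmed-mean-of-M-values scaling factors: the reference sample
#' is the one whose 75th-percentile CPM is closest to the mean of those;
#' each sample's factor is the weighted mean of M-values (log2 ratios to the
#' reference) after double trimming (30% on M, 5% on A by default) over
#' genes positive in both samples, and the factors are rescaled to geometric
#' mean 1. Computed by edgeR's TMM implementation.
#'
#' @param counts A [count_matrix()], or a non-negative numeric matrix (e.g.
#'   a reads-per-kilobase matrix for GeTMM).
#' @param trim_m Trim fraction on M-values (default 0.30).
#' @param trim_a Trim fraction on A-values (default 0.05).
#' @return A tibble with columns `sample`, `lib_size`, `factor` and
#'   `is_reference`; the reference sample id is in `attr(, "reference_sample")`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  m <- if (inherits(counts, "count_mat")) counts$counts else counts
  if (ncol(m) < 2) abort("TMM needs >= 2 samples")
  lib <- colSums(m)
  if (any(lib == 0)) {
    abort(paste0("all-zero sample(s): ",
                 paste(colnames(m)[lib == 0], collapse = ", ")))
  }
  if (!any(rowSums(m > 0) == ncol(m))) {
    abort("no gene is expressed in all samples; TMM is undefined")
  }
  f75 <- apply(m, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(f75 - mean(f75)))
  f <- edgeR::calcNormFactors(m, lib.size = lib, method = "TMM",
                              refColumn = ref, logratioTrim = trim_m,
                              sumTrim = trim_a)
  out <- tibble(
    sample = colnames(m),
    lib_size = as.numeric(lib),
    factor = as.numeric(f),
    is_reference = seq_len(ncol(m)) == ref
  )
  attr(out, "reference_sample") <- colnames(m)[ref]
  out
}

#' GeTMM normalization of a count matrix
#'
#' Gene-length-corrected TMM: counts are first converted to reads per
#' kilobase, `RPK = count / (length / 1000)`; TMM factors are computed on
#' the RPK matrix; and each sample is scaled to
#' `GeTMM = RPK / (sum(RPK) * factor) * 1e6`, so per-sample totals equal
#' `1e6 / factor`. Values are linear; apply [log2p1()] downstream.
#'
#' @param counts A [count_matrix()].
#' @param factors Optional precomputed [tmm_factors()] on the RPK matrix;
#'   computed internally when `NULL`.
#' @param trim_m,trim_a Trim fractions passed to [tmm_factors()].
#' @return An [expression_matrix()] of linear GeTMM values, with the factor
#'   table in `attr(, "factors")`.
#' @export
getmm_normalize <- function(counts, factors = NULL, trim_m = 0.30,
                            trim_a = 0.05) {
  stopifnot(inherits(counts, "count_mat"))
  rpk <- counts$counts / (counts$gene_lengths / 1000)
  factors <- factors %||% if (ncol(rpk) == 1) {
    # a single sample has nothing to be normalized against
    tibble(sample = colnames(rpk), lib_size = sum(counts$counts),
           factor = 1, is_reference = TRUE)
  } else {
    tmm_factors(rpk, trim_m = trim_m, trim_a = trim_a)
  }
  if (!identical(factors$sample, colnames(rpk))) {
    abort("factor table does not match the count matrix samples")
  }
  denom <- colSums(rpk) * factors$factor
  getmm <- sweep(rpk, 2, denom, "/") * 1e6
  out <- expression_matrix(getmm, counts$design)
  attr(out, "factors") <- factors
  out
}

#' Remove genes with low expression in any sample
#'
#' The default mode removes every gene whose `log2(GeTMM + 1)` is `<= 0` in
#' at least one sample, i.e. genes with a zero in any sample (log2 of 0 is
#' undefined, so the +1 is applied inside the log). `strict_literal` instead
#' reads the cutoff as `log2(GeTMM) + 1 <= 0`, i.e. removes genes with
#' `GeTMM <= 0.5` in at least one sample.
#'
#' @param expr An [expression_matrix()] of linear, non-negative values.
#' @param mode `"log2_plus1"` (default) or `"strict_literal"`.
#' @return The filtered [expression_matrix()]; removed gene ids are in
#'   `attr(, "removed_genes")`. Idempotent.
#' @export
filter_low_expression <- function(expr, mode = c("log2_plus1", "strict_literal")) {
  stopifnot(inherits(expr, "expr_mat"))
  mode <- match.arg(mode)
  if (any(expr$values < 0)) abort("expected linear values >= 0")
  low <- if (mode == "log2_plus1") {
    log2(expr$values + 1) <= 0
  } else {
    expr$values <= 0.5
  }
  drop <- rowSums(low) > 0
  inform(paste0("filter_low_expression (", mode, "): removed ", sum(drop),
                " of ", length(drop), " genes"))
  out <- expression_matrix(expr$values[!drop, , drop = FALSE], expr$design)
  attr(out, "removed_genes") <- rownames(expr$values)[drop]
  out
}
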