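#' Expression matrix bound to a stage design
#'
#' A genes-by-samples matrix of (typically log-scale) expression values,
#' validated against a [stage_design()]. Values must be finite: missing
#' values are rejected at construction, never imputed.
#'
#' @param values A numeric matrix with gene ids as rownames and sample ids as
#'   colnames, or a data frame whose first column holds gene ids and whose
#'   remaining columns are one sample each.
#' @param design A [stage_design()], or `NULL` for a matrix not (yet) tied to
#'   a staged layout (e.g. freshly normalized counts).
#'
#' @return An object of class `expr_mat`.
#' @export
expression_matrix <- function(values, design = NULL) {
  values <- as_gene_matrix(values)
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    abort(paste0("duplicated gene id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    dup <- unique(colnames(values)[duplicated(colnames(values))])
    abort(paste0("duplicated sample id(s): ", paste(head(dup, 5), collapse = ", ")))
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort(paste0("non-finite expression value at gene '",
                 rownames(values)[bad[1]], "', sample '",
                 colnames(values)[bad[2]],
                 "' (missing values are rejected, not imputed)"))
  }
  if (!is.null(design)) {
    stopifnot(inherits(design, "stage_design"))
    missing_samples <- setdiff(colnames(values), design$samples$sample)
    if (length(missing_samples) > 0) {
      abort(paste0("sample(s) absent from the sample sheet: ",
                   paste(missing_samples, collapse = ", ")))
    }
  }
  structure(list(values = values, design = design), class = "expr_mat")
}

as_gene_matrix <- function(values) {
  if (is.data.frame(values)) {
    ids <- as.character(values[[1]])
    m <- as.matrix(values[-1])
    if (!is.numeric(m)) {
      bad <- which(!vapply(values[-1], is.numeric, logical(1)))[1]
      abort(paste0("non-numeric expression column: '", names(values[-1])[bad], "'"))
    }
    rownames(m) <- ids
    m
  } else if (is.matrix(values)) {
    if (!is.numeric(values)) abort("expression matrix must be numeric")
    if (is.null(rownames(values)) || is.null(colnames(values))) {
      abort("expression matrix needs gene ids as rownames and sample ids as colnames")
    }
    values
  } else {
    abort("`values` must be a matrix or data frame")
  }
}

#' @export
print.expr_mat <- function(x, ...) {
  cat("<expr_mat> ", nrow(x$values), " genes x ", ncol(x$values), " samples\n",
      sep = "")
  if (!is.null(x$design)) {
    cat("  stages: ", paste(x$design$stages, collapse = ", "),
        " (reference ", x$design$reference_stage, ")\n", sep = "")
  }
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Gene and sample ids of an expression matrix
#' @param expr An [expression_matrix()].
#' @return Character vector.
#' @export
gene_ids <- function(expr) rownames(expr$values)

#' @rdname gene_ids
#' @export
sample_ids <- function(expr) colnames(expr$values)

#' @export
as.matrix.expr_mat <- function(x, ...) x$values

#' Long-format view of an expression matrix
#'
#' @param x An [expression_matrix()].
#' @param ... Unused.
#' @return A tibble with columns `gene_id`, `sample`, `value` and, when a
#'   design is attached, `stage` and `replicate`.
#' @export
as_tibble.expr_mat <- function(x, ...) {
  out <- tibble(
    gene_id = rep(rownames(x$values), times = ncol(x$values)),
    sample = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
  if (!is.null(x$design)) {
    out <- left_join(out, x$design$samples, by = "sample")
  }
  out
}

#' Extract the submatrix of one stage's replicate columns
#' @param expr An [expression_matrix()] with a design.
#' @param stage Stage label.
#' @return Numeric matrix (genes x replicates).
#' @export
stage_values <- function(expr, stage) {
  if (is.null(expr$design)) abort("expression matrix has no stage design")
  expr$values[, stage_samples(expr$design, stage), drop = FALSE]
}

#' Apply log2(x + 1) to a linear-scale expression matrix
#' @param expr An [expression_matrix()] of non-negative linear values.
#' @return An [expression_matrix()] of log2(x + 1) values.
#' @export
log2p1 <- function(expr) {
  stopifnot(inherits(expr, "expr_mat"))
  expression_matrix(log2(expr$values + 1), expr$design)
}

#' Count matrix with gene lengths for GeTMM normalization
#'
#' @param counts Non-negative integer matrix (genes x samples) or data frame
#'   (first column gene ids).
#' @param gene_lengths A data frame with columns `gene` and `length_bp`, or a
#'   named numeric vector of lengths in base pairs.
#' @param design Optional [stage_design()].
#' @return An object of class `count_mat`.
#' @export
count_matrix <- function(counts, gene_lengths, design = NULL) {
  counts <- as_gene_matrix(counts)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    abort("counts must be finite and non-negative")
  }
  if (any(abs(counts - round(counts)) > 1e-8)) {
    abort("counts must be integral")
  }
  if (is.data.frame(gene_lengths)) {
    gl <- setNames(as.numeric(gene_lengths$length_bp),
                   as.character(gene_lengths$gene))
  } else {
    gl <- gene_lengths
  }
  missing_len <- setdiff(rownames(counts), names(gl))
  if (length(missing_len) > 0) {
    abort(paste0("gene length missing for counted gene(s): ",
                 paste(head(missing_len, 5), collapse = ", ")))
  }
  gl <- gl[rownames(counts)]
  if (any(!is.finite(gl)) || any(gl <= 0)) {
    abort("every gene length must be a positive number of base pairs")
  }
  structure(list(counts = counts, gene_lengths = gl, design = design),
            class = "count_mat")
}

#' @export
print.count_mat <- function(x, ...) {
  cat("<count_mat> ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  invisible(x)
}

#' @export
dim.count_mat <- function(x) dim(x$counts)
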