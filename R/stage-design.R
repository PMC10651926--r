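#' Describe the stage/replicate layout of an experiment
#'
#' A stage design records which developmental stage and biological replicate
#' each sample belongs to, plus the designated reference stage against which
#' per-stage statistics (fold-change of SD, candidate tests, ratios) are
#' computed. In the motivating cassava storage-root system the layout is four
#' stages (FR4, FR8, IR8, SR8) in triplicate with FR4 as reference.
#'
#' @param samples A data frame with columns `sample`, `stage`, `replicate`
#'   (one row per sample). Stage order is taken from the order of first
#'   appearance unless `stages` is given.
#' @param reference Reference stage label. Defaults to the first stage.
#' @param stages Optional explicit stage ordering.
#'
#' @return An object of class `stage_design`: a list with elements `stages`
#'   (ordered character), `samples` (tibble of sample, stage, replicate) and
#'   `reference_stage`.
#' @export
#' @examples
#' sheet <- tibble::tibble(
#'   sample = paste0("s", 1:6),
#'   stage = rep(c("FR4", "FR8"), each = 3),
#'   replicate = rep(1:3, 2)
#' )
#' stage_design(sheet, reference = "FR4")
stage_design <- function(samples, reference = NULL, stages = NULL) {
  samples <- as_tibble(samples)
  need <- c("sample", "stage", "replicate")
  missing_cols <- setdiff(need, names(samples))
  if (length(missing_cols) > 0) {
    abort(paste0("sample sheet is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  samples <- samples[need]
  samples$sample <- as.character(samples$sample)
  samples$stage <- as.character(samples$stage)
  samples$replicate <- as.integer(samples$replicate)

  dup <- samples$sample[duplicated(samples$sample)]
  if (length(dup) > 0) {
    abort(paste0("duplicated sample id(s): ", paste(unique(dup), collapse = ", ")))
  }
  dup_rep <- samples |>
    count(.data$stage, .data$replicate) |>
    filter(n > 1)
  if (nrow(dup_rep) > 0) {
    abort(paste0("replicate indices are not distinct within stage(s): ",
                 paste(unique(dup_rep$stage), collapse = ", ")))
  }

  stages <- stages %||% unique(samples$stage)
  if (!setequal(stages, unique(samples$stage))) {
    abort("`stages` must contain exactly the stage labels present in `samples`")
  }
  reference <- reference %||% stages[[1]]
  if (!reference %in% stages) {
    abort(paste0("reference stage '", reference, "' is not among the stages"))
  }

  n_rep <- table(samples$stage)
  small <- names(n_rep)[n_rep < 2]
  if (length(small) > 0) {
    abort(paste0("every stage needs >= 2 replicates (SD and tests require it); ",
                 "offending stage(s): ", paste(small, collapse = ", ")))
  }

  samples$stage <- factor(samples$stage, levels = stages)
  samples <- arrange(samples, .data$stage, .data$replicate)
  samples$stage <- as.character(samples$stage)

  structure(
    list(stages = as.character(stages),
         samples = samples,
         reference_stage = reference),
    class = "stage_design"
  )
}

#' @export
print.stage_design <- function(x, ...) {
  cat("<stage_design> ", length(x$stages), " stages, ",
      nrow(x$samples), " samples\n", sep = "")
  reps <- table(factor(x$samples$stage, levels = x$stages))
  cat("  stages: ",
      paste0(x$stages, " (", as.integer(reps), ")", collapse = ", "), "\n",
      sep = "")
  cat("  reference: ", x$reference_stage, "\n", sep = "")
  invisible(x)
}

#' Samples belonging to one stage
#' @param design A [stage_design()].
#' @param stage Stage label.
#' @return Character vector of sample ids, in replicate order.
#' @export
stage_samples <- function(design, stage) {
  stopifnot(inherits(design, "stage_design"))
  if (!stage %in% design$stages) {
    abort(paste0("unknown stage '", stage, "'"))
  }
  design$samples$sample[design$samples$stage == stage]
}

#' Non-reference stages of a design, in design order
#' @param design A [stage_design()].
#' @return Character vector.
#' @export
nonreference_stages <- function(design) {
  setdiff(design$stages, design$reference_stage)
}
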