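#' Read a tab-delimited expression matrix and its sample sheet
#'
#' The matrix file carries gene ids in the first column and one sample per
#' remaining column; the sample sheet has columns `sample`, `stage`,
#' `replicate`. Lines starting with `#` are ignored in both files. Gene and
#' sample order is preserved from the files.
#'
#' @param matrix_path Path to the expression TSV.
#' @param sample_sheet_path Path to the sample sheet TSV.
#' @param reference Reference stage (default: first stage in the sheet).
#' @return An [expression_matrix()].
#' @export
read_expression <- function(matrix_path, sample_sheet_path, reference = NULL) {
  design <- stage_design(read_sample_sheet(sample_sheet_path),
                         reference = reference)
  tbl <- read_tsv_strict(matrix_path)
  for (j in seq_along(tbl)[-1]) {
    if (!is.numeric(tbl[[j]])) {
      abort(paste0("non-numeric cell(s) in expression column '",
                   names(tbl)[j], "' of ", matrix_path))
    }
  }
  expression_matrix(tbl, design)
}

#' @rdname read_expression
#' @param path Path to a sample sheet TSV.
#' @export
read_sample_sheet <- function(path) {
  tbl <- read_tsv_strict(path)
  need <- c("sample", "stage", "replicate")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0(path, " is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl
}

read_tsv_strict <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE)
  probs <- readr::problems(tbl)
  if (nrow(probs) > 0) {
    abort(paste0("malformed TSV ", path, " (first problem at line ",
                 probs$row[1], ", column ", probs$col[1], ")"))
  }
  tbl
}

#' Write an expression or count matrix (and its sample sheet) as TSV
#'
#' Values are written in full precision (`%.15g`), so a write/read round
#' trip is lossless well beyond 12 significant digits.
#'
#' @param expr An [expression_matrix()] or [count_matrix()].
#' @param matrix_path Output path for the matrix TSV.
#' @param sample_sheet_path Optional output path for the sample sheet.
#' @return `matrix_path`, invisibly.
#' @export
write_expression <- function(expr, matrix_path, sample_sheet_path = NULL) {
  m <- if (inherits(expr, "count_mat")) expr$counts else expr$values
  tbl <- as.data.frame(m)
  tbl <- cbind(gene_id = rownames(m), tbl)
  write_tsv_full(tbl, matrix_path)
  if (!is.null(sample_sheet_path)) {
    if (is.null(expr$design)) abort("no design attached; cannot write sample sheet")
    write_tsv_full(expr$design$samples, sample_sheet_path)
  }
  invisible(matrix_path)
}

#' Write any tabular result as TSV with full numeric precision
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_full <- function(x, path) {
  x <- as.data.frame(x)
  num <- vapply(x, is.numeric, logical(1)) & !vapply(x, is.integer, logical(1))
  x[num] <- lapply(x[num], function(v) sprintf("%.15g", v))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a probe-to-gene annotation table
#'
#' Expected columns: `probe_id`, `gene_id`, `evalue`, `identity_pct`,
#' `bidirectional` (logical or 0/1). One record per (probe, gene) pair.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble of annotation records.
#' @export
read_probe_annotation <- function(path) {
  tbl <- read_tsv_strict(path)
  probe_annotation(tbl)
}

#' Validate a probe annotation table
#' @param tbl Data frame with columns `probe_id`, `gene_id`, `evalue`,
#'   `identity_pct`, `bidirectional`.
#' @return A validated tibble.
#' @export
probe_annotation <- function(tbl) {
  tbl <- as_tibble(tbl)
  need <- c("probe_id", "gene_id", "evalue", "identity_pct", "bidirectional")
  missing_cols <- setdiff(need, names(tbl))
  if (length(missing_cols) > 0) {
    abort(paste0("probe annotation is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  tbl <- tbl[need]
  tbl$probe_id <- as.character(tbl$probe_id)
  tbl$gene_id <- as.character(tbl$gene_id)
  tbl$bidirectional <- as.logical(tbl$bidirectional)
  if (any(!is.finite(tbl$evalue)) || any(tbl$evalue < 0)) {
    abort("probe annotation: evalue must be finite and >= 0")
  }
  if (any(tbl$identity_pct < 0 | tbl$identity_pct > 100)) {
    abort("probe annotation: identity_pct must lie in [0, 100]")
  }
  dup <- duplicated(tbl[c("probe_id", "gene_id")])
  if (any(dup)) {
    abort(paste0("probe annotation: duplicated (probe, gene) pair(s), e.g. (",
                 tbl$probe_id[dup][1], ", ", tbl$gene_id[dup][1], ")"))
  }
  tbl
}

#' Read and write GMT gene-set collections
#'
#' GMT dialect: one set per line, `name TAB description TAB member...`.
#'
#' @param path Path to a GMT file.
#' @return A named list of character vectors (class `gene_set_collection`),
#'   with per-set descriptions in `attr(x, "descriptions")`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    parts <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) {
      abort(paste0("malformed GMT line ", i, " in ", path,
                   ": need name, description and >= 1 member"))
    }
    nm <- parts[[1]]
    if (nm %in% names(sets)) {
      abort(paste0("duplicated gene-set name '", nm, "' at GMT line ", i))
    }
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0) {
      abort(paste0("empty member list at GMT line ", i, " in ", path))
    }
    sets[[nm]] <- members
    desc[[nm]] <- parts[[2]]
  }
  structure(sets, descriptions = desc, class = "gene_set_collection")
}

#' @rdname read_gmt
#' @param collection A named list of character vectors.
#' @param descriptions Optional named character vector of descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  descriptions <- descriptions %||% attr(collection, "descriptions") %||%
    setNames(rep("", length(collection)), names(collection))
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, descriptions[[nm]] %||% "", collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a TF-to-target regulatory edge list
#'
#' Expected columns `tf` and `target` (PlantRegMap-style TSV; extra columns
#' are ignored). Duplicate edges are collapsed and their multiplicity kept
#' in `n_records`; self-loops are dropped unless `keep_self_loops`.
#'
#' @param path Path to the edge TSV.
#' @param keep_self_loops Keep tf == target edges? Default `FALSE`.
#' @return A tibble with columns `tf`, `target`, `n_records`.
#' @export
read_edges <- function(path, keep_self_loops = FALSE) {
  tbl <- read_tsv_strict(path)
  if (ncol(tbl) < 2) abort(paste0(path, ": need at least 2 columns (tf, target)"))
  if (!all(c("tf", "target") %in% names(tbl))) {
    names(tbl)[1:2] <- c("tf", "target")
  }
  regulatory_edges(tbl, keep_self_loops = keep_self_loops)
}

#' @rdname read_edges
#' @param edges Data frame with columns `tf` and `target`.
#' @export
regulatory_edges <- function(edges, keep_self_loops = FALSE) {
  edges <- as_tibble(edges)
  edges$tf <- as.character(edges$tf)
  edges$target <- as.character(edges$target)
  loops <- edges$tf == edges$target
  if (any(loops) && !keep_self_loops) {
    inform(paste0("dropped ", sum(loops), " self-loop edge(s)"))
    edges <- edges[!loops, ]
  }
  edges |>
    count(.data$tf, .data$target, name = "n_records") |>
    arrange(.data$tf, .data$target)
}

#' Read gene-to-term annotations (e.g. GO)
#'
#' Expected columns `gene`, `term` and optionally `name`, `namespace`.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble.
#' @export
read_term_annotations <- function(path) {
  tbl <- read_tsv_strict(path)
  if (!all(c("gene", "term") %in% names(tbl))) {
    abort(paste0(path, ": need columns 'gene' and 'term'"))
  }
  tbl$gene <- as.character(tbl$gene)
  tbl$term <- as.character(tbl$term)
  distinct(tbl)
}

#' Read a minimal ontology file (id / name / namespace / is_a records)
#'
#' Supports a restricted OBO-like dialect: stanzas starting with `[Term]`,
#' and `id:`, `name:`, `namespace:` and `is_a:` lines. Only `is_a`
#' parentage is read; other relationship types are out of scope.
#'
#' @param path Path to the ontology file.
#' @return A list with tibbles `terms` (term, name, namespace) and
#'   `parents` (term, parent).
#' @export
read_ontology <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- trimws(readLines(path, encoding = "UTF-8"))
  terms <- list()
  parents <- list()
  cur <- NULL
  flush <- function(cur) {
    if (is.null(cur) || is.null(cur$id)) return(NULL)
    cur
  }
  in_term <- FALSE
  for (ln in lines) {
    if (ln == "[Term]") {
      if (in_term && !is.null(cur$id)) {
        terms[[cur$id]] <- cur
      }
      cur <- list(id = NULL, name = NA_character_, namespace = NA_character_,
                  parents = character())
      in_term <- TRUE
    } else if (grepl("^\\[", ln)) {
      if (in_term && !is.null(cur$id)) terms[[cur$id]] <- cur
      in_term <- FALSE
    } else if (in_term && grepl("^id:", ln)) {
      cur$id <- trimws(sub("^id:", "", ln))
    } else if (in_term && grepl("^name:", ln)) {
      cur$name <- trimws(sub("^name:", "", ln))
    } else if (in_term && grepl("^namespace:", ln)) {
      cur$namespace <- trimws(sub("^namespace:", "", ln))
    } else if (in_term && grepl("^is_a:", ln)) {
      parent <- trimws(sub("^is_a:", "", ln))
      parent <- trimws(strsplit(parent, "!", fixed = TRUE)[[1]][1])
      cur$parents <- c(cur$parents, parent)
    }
  }
  if (in_term && !is.null(cur$id)) terms[[cur$id]] <- cur
  term_tbl <- bind_rows(lapply(terms, function(t) {
    tibble(term = t$id, name = t$name, namespace = t$namespace)
  }))
  parent_tbl <- bind_rows(lapply(terms, function(t) {
    if (length(t$parents) == 0) return(NULL)
    tibble(term = t$id, parent = t$parents)
  }))
  if (is.null(parent_tbl) || nrow(parent_tbl) == 0) {
    parent_tbl <- tibble(term = character(), parent = character())
  }
  list(terms = term_tbl, parents = parent_tbl)
}
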