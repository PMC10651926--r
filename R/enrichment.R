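#' Gene-set overlap odds ratio and Fisher's exact test
#'
#' Encodes the overlap of a query set and a reference set within a gene
#' universe as the 2x2 table a = query-and-set, b = query-only,
#' c = set-only, d = neither, and reports the odds ratio `(a*d)/(b*c)` —
#' with the Haldane-Anscombe +0.5 correction applied (and flagged) only
#' when some cell is zero — together with the two-sided Fisher exact
#' p-value (point-probability rule: sum over tables as or less probable
#' than the observed one).
#'
#' @param query,reference Character vectors of gene ids, subsets of
#'   `universe`.
#' @param universe Character vector of at least 2 gene ids.
#' @return A one-row tibble: `odds_ratio`, `p_value`, `a`, `b`, `c`, `d`,
#'   `haldane_corrected`.
#' @export
#' @examples
#' overlap_odds_ratio(paste0("g", 1:10), paste0("g", c(1:5, 11:25)),
#'                    paste0("g", 1:100))
overlap_odds_ratio <- function(query, reference, universe) {
  universe <- unique(universe)
  if (length(universe) < 2) abort("universe must contain >= 2 genes")
  query <- unique(query); reference <- unique(reference)
  out_q <- setdiff(query, universe)
  out_r <- setdiff(reference, universe)
  if (length(out_q) > 0 || length(out_r) > 0) {
    abort(paste0("gene(s) outside the universe: ",
                 paste(head(c(out_q, out_r), 5), collapse = ", ")))
  }
  a <- length(intersect(query, reference))
  b <- length(setdiff(query, reference))
  cc <- length(setdiff(reference, query))
  d <- length(universe) - a - b - cc
  haldane <- any(c(a, b, cc, d) == 0)
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (cc + 0.5))
  } else {
    (a * d) / (b * cc)
  }
  p <- fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE))$p.value
  tibble(odds_ratio = or, p_value = p, a = a, b = b, c = cc, d = d,
         haldane_corrected = haldane)
}

#' GO term enrichment by hypergeometric test
#'
#' For each term, the upper-tail hypergeometric probability
#' `P(X >= k | N, K, n)` of observing `k` query genes annotated to a term
#' of size `K` in a universe of `N` genes given a query of size `n`,
#' followed by BH adjustment across the tested terms. By default only
#' terms with at least one query hit are tested (matching the convention
#' of the common GO tooling); `test_all_terms` tests every annotated term,
#' which changes the BH denominator. Both "gene ratio" conventions are
#' emitted: `gene_ratio` = k/n (fraction of the query annotated to the
#' term) and `gene_ratio_genome` = k/K (query hits over all genes in the
#' universe annotated to the term).
#'
#' @param query Character vector of gene ids, a subset of `universe`.
#' @param annotations Tibble with columns `gene`, `term` and optionally
#'   `name`, `namespace`; restricted to the universe.
#' @param universe Character vector of gene ids.
#' @param alpha BH FDR cutoff flagged in `significant` (default 0.05).
#' @param test_all_terms Test terms with zero query hits too? Default
#'   `FALSE`.
#' @return A tibble with one row per tested term: `term`, `name`, `k`,
#'   `K`, `n`, `N`, `gene_ratio`, `gene_ratio_genome`, `p_value`,
#'   `q_value`, `significant`, `genes` (list column of the query hits).
#' @export
go_enrichment <- function(query, annotations, universe, alpha = 0.05,
                          test_all_terms = FALSE) {
  universe <- unique(universe)
  query <- unique(query)
  bad <- setdiff(query, universe)
  if (length(bad) > 0) {
    abort(paste0("query gene(s) outside the universe: ",
                 paste(head(bad, 5), collapse = ", ")))
  }
  annotations <- as_tibble(annotations)
  if (nrow(annotations) == 0) abort("empty annotation map")
  if (!"name" %in% names(annotations)) annotations$name <- NA_character_
  annotations <- annotations |>
    filter(.data$gene %in% universe) |>
    distinct(.data$gene, .data$term, .keep_all = TRUE)
  if (nrow(annotations) == 0) {
    abort("no annotation refers to a universe gene")
  }

  nn <- length(query)
  NN <- length(universe)
  per_term <- annotations |>
    group_by(.data$term) |>
    summarise(
      name = .data$name[1],
      K = dplyr::n_distinct(.data$gene),
      genes = list(sort(intersect(.data$gene, query))),
      .groups = "drop"
    ) |>
    mutate(k = lengths(.data$genes))
  if (!test_all_terms) per_term <- filter(per_term, .data$k >= 1)
  if (nrow(per_term) == 0) {
    return(tibble(term = character(), name = character(), k = integer(),
                  K = integer(), n = integer(), N = integer(),
                  gene_ratio = numeric(), gene_ratio_genome = numeric(),
                  p_value = numeric(), q_value = numeric(),
                  significant = logical(), genes = list()))
  }
  p <- phyper(per_term$k - 1, per_term$K, NN - per_term$K, nn,
              lower.tail = FALSE)
  q <- benjamini_hochberg(p)
  per_term |>
    mutate(n = nn, N = NN,
           gene_ratio = .data$k / nn,
           gene_ratio_genome = .data$k / .data$K,
           p_value = p, q_value = q,
           significant = q <= alpha) |>
    select("term", "name", "k", "K", "n", "N", "gene_ratio",
           "gene_ratio_genome", "p_value", "q_value", "significant",
           "genes") |>
    arrange(.data$p_value, .data$term)
}

#' Close gene annotations under is_a ancestry (true-path rule)
#'
#' Every gene annotated to a term gains the term's ancestors along the
#' `is_a` parent graph. The parent graph must be acyclic; cycles are
#' reported with the offending terms. Idempotent.
#'
#' @param annotations Tibble with columns `gene`, `term` (extra columns
#'   for newly added ancestor rows are filled with `NA`).
#' @param parents Tibble with columns `term`, `parent`.
#' @return The closed annotation tibble (distinct gene/term pairs).
#' @export
propagate_annotations <- function(annotations, parents) {
  annotations <- as_tibble(annotations)
  parents <- as_tibble(parents)
  if (nrow(parents) == 0) return(distinct(annotations))
  ancestors <- ancestor_closure(parents)
  extra <- annotations |>
    select("gene", "term") |>
    dplyr::inner_join(ancestors, by = "term",
                      relationship = "many-to-many") |>
    select("gene", term = "ancestor") |>
    distinct()
  out <- bind_rows(annotations, extra) |>
    arrange(.data$gene, .data$term)
  distinct(out, .data$gene, .data$term, .keep_all = TRUE)
}

# term -> all ancestors along is_a edges; errors on a cycle, naming it
ancestor_closure <- function(parents) {
  adj <- split(parents$parent, parents$term)
  memo <- new.env(parent = emptyenv())
  visit <- function(term, path) {
    if (term %in% path) {
      cyc <- c(path[seq(match(term, path), length(path))], term)
      abort(paste0("cycle in is_a graph: ", paste(cyc, collapse = " -> ")))
    }
    if (!is.null(memo[[term]])) return(memo[[term]])
    ps <- adj[[term]]
    if (is.null(ps)) {
      memo[[term]] <- character(0)
      return(character(0))
    }
    anc <- unique(c(ps, unlist(lapply(ps, visit, path = c(path, term)))))
    memo[[term]] <- anc
    anc
  }
  terms <- unique(parents$term)
  res <- lapply(terms, visit, path = character(0))
  bind_rows(purrr::map2(terms, res, function(t, a) {
    if (length(a) == 0) return(NULL)
    tibble(term = t, ancestor = a)
  }))
}
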