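#' Hypergeometric overlap test between two gene sets
#'
#' Tests whether the overlap between two gene sets drawn from a common
#' universe is larger than expected by chance: with `N` universe genes of
#' which `K` are in `set_a` and a sample of `n = |set_b|`, the p-value is
#' the inclusive upper tail `P(X >= k)` of the hypergeometric
#' distribution at the observed overlap `k`.
#'
#' @param set_a,set_b Character vectors of gene identifiers; both must be
#'   subsets of `universe`. Duplicates are removed.
#' @param universe Character vector of all eligible genes (for enrichment
#'   comparisons, typically the genes passing the expression filter in
#'   both experiments).
#' @return A one-row tibble: `n_universe`, `n_a`, `n_b`, `overlap`,
#'   `expected`, `p_value`.
#' @export
#' @examples
#' hypergeometric_overlap(letters[1:5], letters[3:7], letters)
hypergeometric_overlap <- function(set_a, set_b, universe) {
  universe <- unique(as.character(universe))
  set_a <- unique(as.character(set_a))
  set_b <- unique(as.character(set_b))
  if (!all(set_a %in% universe) || !all(set_b %in% universe)) {
    abort("both sets must be subsets of the universe",
          class = "periloc_invalid_sets")
  }
  N <- length(universe)
  K <- length(set_a)
  n <- length(set_b)
  k <- length(intersect(set_a, set_b))
  p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  tibble::tibble(n_universe = N, n_a = K, n_b = n, overlap = k,
                 expected = K * n / N, p_value = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up procedure: `adjusted_i = min over j >= rank(i)` of
#' `m * p_(j) / j`, capped at 1 and order-preserving.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1)) {
    abort("p-values must lie in [0, 1]", class = "periloc_invalid_input")
  }
  p.adjust(p_values, method = "BH")
}

#' Overlap of a query gene list against a gene-set collection
#'
#' Runs [hypergeometric_overlap()] of one query list against every set in
#' a collection (for example read with [read_gmt()]), restricting each set
#' to the universe, and adjusts the p-values with [bh_adjust()].
#'
#' @param query Character vector of genes (subset of `universe`).
#' @param gene_sets Named list of character vectors.
#' @param universe Character vector of eligible genes.
#' @return A tibble with one row per gene set: `set`, `set_size` (within
#'   the universe), `overlap`, `expected`, `p_value`, `p_adjusted`,
#'   sorted by p-value.
#' @export
gene_set_overlap <- function(query, gene_sets, universe) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  universe <- unique(as.character(universe))
  rows <- purrr::imap(gene_sets, function(genes, name) {
    genes <- intersect(unique(as.character(genes)), universe)
    res <- hypergeometric_overlap(genes, query, universe)
    tibble::tibble(set = name, set_size = length(genes),
                   overlap = res$overlap, expected = res$expected,
                   p_value = res$p_value)
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(p_adjusted = bh_adjust(.data$p_value)) |>
    dplyr::arrange(.data$p_value)
}
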