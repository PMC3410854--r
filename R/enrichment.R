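#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: the chance of drawing
#' at least `k` category members when `n` genes are sampled without
#' replacement from a universe of `N` genes of which `K` belong to the
#' category. This is the standard one-sided over-representation test;
#' the tail is evaluated with `stats::phyper`, which works in log space
#' internally and is exact for small `N`.
#'
#' @param k observed overlap (selected genes in the category).
#' @param K category size within the universe.
#' @param n selection size.
#' @param N universe size.
#' @return the tail probability, vectorized over its arguments.
#' @export
hypergeometric_tail <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | k > n | k > K | n > N | K > N
  if (any(bad)) {
    abort("counts must satisfy 0 <= k <= min(n, K) and n, K <= N.")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Category over-representation in a gene list
#'
#' Tests each category for enrichment in `selected` against the
#' hypergeometric null, reporting the overlap count, the percentage of
#' the selection in the category (the "(P, %)" convention of
#' over-representation reports) and the one-sided p-value. Category
#' memberships are intersected with the universe first.
#'
#' @param selected character vector of selected gene ids (must be a
#'   subset of `universe`).
#' @param categories tibble with `gene_id`, `category` (one membership
#'   per row), or a named list of gene-id vectors.
#' @param universe character vector of all eligible gene ids.
#' @param adjust apply Benjamini-Hochberg correction in an extra
#'   `p_adjusted` column.
#' @return tibble with `category`, `k`, `n`, `K`, `N`, `percent`,
#'   `p_value`, sorted by `p_value`.
#' @export
category_enrichment <- function(selected, categories, universe,
                                adjust = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("`universe` is empty.")
  selected <- unique(selected)
  if (!all(selected %in% universe)) {
    abort("`selected` must be a subset of `universe`.")
  }
  if (is.data.frame(categories)) {
    categories <- split(categories$gene_id, categories$category)
  }
  n <- length(selected)
  N <- length(universe)
  out <- purrr::imap_dfr(categories, function(members, name) {
    members <- intersect(unique(members), universe)
    K <- length(members)
    k <- length(intersect(members, selected))
    tibble(category = name, k = k, n = n, K = K, N = N,
           percent = 100 * k / n,
           p_value = hypergeometric_tail(k, K, n, N))
  }) |>
    arrange(.data$p_value, .data$category)
  if (adjust) out$p_adjusted <- p.adjust(out$p_value, method = "BH")
  out
}

#' Overlap between a gene list and an occupancy class
#'
#' One hypergeometric tail for the overlap of an externally defined gene
#' list (e.g. genes down-regulated in a mutant) with one occupancy class
#' (e.g. the highest-occupancy quartile), both taken within `universe`.
#'
#' @param list_a character vector of gene ids (the selection).
#' @param class_b character vector of gene ids (the class).
#' @param universe character vector of all eligible gene ids.
#' @return one-row tibble with `k`, `n`, `K`, `N`, `percent`, `p_value`.
#' @export
list_class_overlap <- function(list_a, class_b, universe) {
  universe <- unique(universe)
  list_a <- unique(list_a)
  class_b <- unique(class_b)
  if (!all(list_a %in% universe) || !all(class_b %in% universe)) {
    abort("both gene lists must be subsets of `universe`.")
  }
  k <- length(intersect(list_a, class_b))
  n <- length(list_a)
  K <- length(class_b)
  N <- length(universe)
  tibble(k = k, n = n, K = K, N = N, percent = 100 * k / n,
         p_value = hypergeometric_tail(k, K, n, N))
}
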