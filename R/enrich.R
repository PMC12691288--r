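#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeom(N, K, n)`: the
#' chance of drawing at least `k` category genes when sampling `n` query
#' genes without replacement from a universe of `N` genes of which `K`
#' belong to the category. Equivalent to the one-sided Fisher exact test.
#'
#' @param k Observed overlap between query and category.
#' @param K Category size within the universe.
#' @param n Query size.
#' @param N Universe size.
#' @return One-sided p-value.
#' @export
#' @examples
#' overrepresentation_p(5, 5, 5, 20)  # 1 / choose(20, 5)
overrepresentation_p <- function(k, K, n, N) {
  bad <- k < 0 | K < 0 | n < 0 | N < 0 | k > K | k > n | K > N | n > N
  if (any(bad)) abort("inconsistent margins: need 0 <= k <= min(K, n) <= N.")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment score from a p-value
#'
#' The natural-log score `-ln(p)` used by common enrichment platforms, so
#' a p-value of 6.77e-65 reports as 147.76.
#'
#' @param p_value P-value(s) in (0, 1].
#' @return Non-negative score(s).
#' @export
enrichment_score <- function(p_value) {
  if (any(!is.finite(p_value)) || any(p_value <= 0 | p_value > 1)) {
    abort("p-values must lie in (0, 1].")
  }
  -log(p_value)
}

#' Over-representation analysis of a gene set
#'
#' Tests every annotation category for over-representation in the query
#' with the hypergeometric upper tail, reports the `-ln(p)` enrichment
#' score and Benjamini-Hochberg step-up FDR across all tested categories.
#' Query genes outside the universe are dropped with a warning; the
#' universe defaults to all annotated genes but should normally be the
#' set of genes actually tested upstream (e.g. all genes with at least
#' one tested transcript).
#'
#' @param query Character vector of gene ids.
#' @param annotation Tibble with columns `category`, `gene` (see
#'   [read_annotation_tsv()]), or a named list of gene-id vectors.
#' @param universe Character vector of gene ids; default: all annotated
#'   genes.
#' @return A tibble sorted by p-value with `category`, `k`, `K`, `n`,
#'   `N`, `p_value`, `enrichment_score`, `fdr`.
#' @export
#' @examples
#' sim <- gen_annotation(sim_config(seed = 3))
#' res <- enrich(sim$query, sim$annotation, sim$universe)
#' head(res, 3)
enrich <- function(query, annotation, universe = NULL) {
  if (is.list(annotation) && !is.data.frame(annotation)) {
    annotation <- tibble(category = rep(names(annotation),
                                        lengths(annotation)),
                         gene = unlist(annotation, use.names = FALSE))
  }
  if (!all(c("category", "gene") %in% names(annotation))) {
    abort("annotation needs `category` and `gene` columns.")
  }
  if (!length(query)) abort("query gene set is empty.")
  universe <- unique(universe %||% annotation$gene)
  if (!all(annotation$gene %in% universe)) {
    annotation <- filter(annotation, .data$gene %in% universe)
  }
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warn(sprintf("%d query gene(s) outside the universe dropped.",
                 length(outside)))
    query <- setdiff(query, outside)
  }
  if (!length(query)) abort("no query genes remain inside the universe.")

  N <- length(universe)
  n <- length(query)
  res <- annotation |>
    distinct(.data$category, .data$gene) |>
    summarise(K = dplyr::n(),
              k = sum(.data$gene %in% query),
              .by = "category") |>
    mutate(n = n, N = N,
           p_value = overrepresentation_p(.data$k, .data$K, n, N),
           enrichment_score = enrichment_score(.data$p_value),
           fdr = fdr_step_up(.data$p_value)) |>
    arrange(.data$p_value, .data$category) |>
    select("category", "k", "K", "n", "N", "p_value",
           "enrichment_score", "fdr")
  res
}
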