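# Over-representation analysis: upper hypergeometric tail of the overlap
# between a query gene list and each gene set, after restriction to a
# stated background universe, with Benjamini-Hochberg correction across
# the tested sets. The background universe is a first-class, logged
# parameter: ORA conclusions are only as good as the background.

#' Hypergeometric over-representation analysis
#'
#' For each collection set, restricted to the universe and size-filtered
#' to `[min_size, max_size]`, computes the upper tail
#' `P(X >= k)` of the hypergeometric distribution with population `N`
#' (universe size), `K` successes (set size in the universe) and `n`
#' draws (query size), identical to the one-sided Fisher exact test on
#' the 2x2 overlap table. Query genes outside the universe are dropped
#' with a message.
#'
#' @param query A [gene_set()] or character vector of query symbols.
#' @param collections Named list of character vectors (e.g. from
#'   [read_gmt()]) or list of [gene_set()] objects.
#' @param universe A [gene_set()] or character vector defining the
#'   background (e.g. all genes surviving the expression and missingness
#'   filters).
#' @param min_size,max_size Set-size bounds after universe restriction
#'   (defaults 5 and 2000).
#' @param cutoff Significance cutoff applied to both the adjusted and the
#'   nominal flags (default 0.05).
#' @return Tibble sorted by ascending p-value: `set_name`, `overlap_k`,
#'   `set_size_K`, `query_size_n`, `universe_size_N`, `p_value`,
#'   `q_value`, `significant_adjusted`, `significant_nominal`,
#'   `overlap_genes` (list column). Attribute `"ora_meta"` records the
#'   universe size, dropped query genes, and set counts.
#' @export
hypergeometric_ora <- function(query, collections, universe,
                               min_size = 5, max_size = 2000,
                               cutoff = 0.05) {
  universe <- unique(as_members(universe))
  if (length(universe) == 0L) abort("empty universe")
  q0 <- unique(as_members(query))
  q <- intersect(q0, universe)
  n_dropped <- length(q0) - length(q)
  if (n_dropped > 0L) {
    inform(sprintf("dropped %d query gene(s) outside the universe", n_dropped))
  }
  if (length(q) == 0L) abort("empty query after restriction to the universe")
  if (is.null(names(collections))) {
    names(collections) <- vapply(collections, function(s) {
      if (inherits(s, "gene_set")) s$name else abort("collections must be named")
    }, character(1L))
  }
  sets <- lapply(collections, function(s) intersect(as_members(s), universe))
  sizes <- lengths(sets)
  tested <- sets[sizes >= min_size & sizes <= max_size]
  N <- length(universe)
  n <- length(q)
  rows <- lapply(names(tested), function(nm) {
    members <- tested[[nm]]
    K <- length(members)
    hits <- intersect(q, members)
    k <- length(hits)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(set_name = nm, overlap_k = k, set_size_K = K,
                   query_size_n = n, universe_size_N = N,
                   p_value = p, overlap_genes = list(sort(hits)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0L) {
    out$q_value <- p.adjust(out$p_value, method = "BH")
    out$significant_adjusted <- out$q_value < cutoff
    out$significant_nominal <- out$p_value < cutoff
    out <- out[order(out$p_value, out$set_name, method = "radix"),
               c("set_name", "overlap_k", "set_size_K", "query_size_n",
                 "universe_size_N", "p_value", "q_value",
                 "significant_adjusted", "significant_nominal",
                 "overlap_genes")]
  } else {
    out <- tibble::tibble(set_name = character(), overlap_k = integer(),
                          set_size_K = integer(), query_size_n = integer(),
                          universe_size_N = integer(), p_value = double(),
                          q_value = double(), significant_adjusted = logical(),
                          significant_nominal = logical(),
                          overlap_genes = list())
  }
  attr(out, "ora_meta") <- list(universe_size = N, query_size = n,
                                query_dropped = n_dropped,
                                n_sets = length(sets),
                                n_sets_tested = length(tested),
                                min_size = min_size, max_size = max_size,
                                cutoff = cutoff)
  out
}
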