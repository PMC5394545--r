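#' Hypergeometric gene-set over-representation
#'
#' For each set, tests whether the query is enriched for the set's members
#' within the universe: with universe size `M`, set size `K` (after
#' intersecting the set with the universe), query size `n` and overlap `k`,
#' the one-tailed p-value is `P(X >= k)` for `X ~ Hypergeometric(M, K, n)`.
#' FDR is Benjamini-Hochberg across all tested sets. Sets empty after
#' universe intersection are skipped.
#'
#' @param query Character vector of gene ids, a subset of `universe`.
#' @param sets Named list of character vectors ([read_gmt()]).
#' @param universe Character vector of all testable gene ids.
#' @return data.frame sorted by p then term: `term`, `k`, `n`, `K`, `M`,
#'   `p_value`, `fdr`.
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (length(universe) == 0L || length(query) == 0L) {
    stop_domain("query and universe must be non-empty")
  }
  if (!all(query %in% universe)) {
    stop_domain("query must be a subset of the universe")
  }
  M <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(term) {
    members <- intersect(sets[[term]], universe)
    K <- length(members)
    if (K == 0L) return(NULL)
    k <- length(intersect(query, members))
    p <- phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, M = M, p_value = p)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), M = integer(0), p_value = numeric(0),
                      fdr = numeric(0)))
  }
  res$fdr <- adjust_q(res$p_value)
  res <- res[order(res$p_value, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Truncate an enrichment table for reporting
#'
#' @param records Sorted output of [hypergeom_enrich()].
#' @param top_n Number of leading terms to keep.
#' @return The first `top_n` rows (whole table if shorter).
#' @export
rank_terms <- function(records, top_n) {
  head(records, top_n)
}
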