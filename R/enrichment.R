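# Hypergeometric over-representation of gene lists against user-supplied
# gene-set collections (GMT input).

#' Hypergeometric over-representation analysis
#'
#' For each term with `K` genes in a universe of `M`, a query of size `n`
#' with `k` hits gets the upper-tail hypergeometric p-value
#' `P(X >= k)`; BH adjustment runs across all tested terms. Query genes
#' outside the universe are dropped with a warning; terms with no genes
#' in the universe are skipped.
#'
#' @param query character vector of gene ids.
#' @param gene_sets named list of gene-id vectors (from [read_gmt()]).
#' @param universe character vector of all eligible gene ids.
#' @return data frame `term`, `k`, `n`, `K`, `M`, `p`, `padj`, `hits`
#'   (comma-separated), sorted by p ascending with ties broken by larger
#'   `k`.
#' @export
hypergeom_enrich <- function(query, gene_sets, universe) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) not in universe; dropped")
    query <- intersect(query, universe)
  }
  n <- length(query)
  M <- length(universe)
  rows <- lapply(names(gene_sets), function(term) {
    set <- intersect(gene_sets[[term]], universe)
    K <- length(set)
    if (K == 0L) return(NULL)
    hits <- intersect(query, set)
    k <- length(hits)
    p <- phyper(k - 1, K, M - K, n, lower.tail = FALSE)
    data.frame(term = term, k = k, n = n, K = K, M = M, p = p,
               hits = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), M = integer(0), p = numeric(0),
                      padj = numeric(0), hits = character(0)))
  res$padj <- bh_adjust(res$p)
  res <- res[order(res$p, -res$k, res$term), ,
             drop = FALSE]
  rownames(res) <- NULL
  res[, c("term", "k", "n", "K", "M", "p", "padj", "hits")]
}

#' Dot-plot-ready enrichment report
#' @param results output of [hypergeom_enrich()].
#' @param top_n number of terms to keep (0 gives an empty table).
#' @return data frame `term`, `count`, `p`, `padj`.
#' @export
enrich_report <- function(results, top_n = 20L) {
  out <- utils::head(results[, c("term", "k", "p", "padj")], top_n)
  names(out)[2L] <- "count"
  rownames(out) <- NULL
  out
}
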