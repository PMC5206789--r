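# Clustering of the genes x tumor-types S-score matrix and hypergeometric
# term enrichment per cluster, with Benjamini-Hochberg adjustment.

#' Cluster genes on their S-score profiles
#'
#' Agglomerative hierarchical clustering of the rows of a genes x tumor-types
#' score matrix (Euclidean distance, Ward linkage, tree cut at `n_clusters`).
#' Missing scores are imputed as 0 (no evidence) with a message.
#'
#' @param s_matrix numeric matrix, genes in rows.
#' @param n_clusters number of groups to cut the tree into (default 3).
#' @param linkage `hclust` method; default `"ward.D2"` (Ward linkage on
#'   Euclidean distances).
#' @param distance `dist` method; default `"euclidean"`.
#' @return named integer vector of cluster labels (1..n_clusters), plus the
#'   dendrogram in attribute `"hclust"`.
#' @export
cluster_genes <- function(s_matrix, n_clusters = 3L, linkage = "ward.D2",
                          distance = "euclidean") {
  if (!is.matrix(s_matrix)) s_matrix <- as.matrix(s_matrix)
  if (n_clusters > nrow(s_matrix)) {
    abort("n_clusters (%d) exceeds number of genes (%d)", n_clusters, nrow(s_matrix))
  }
  if (anyNA(s_matrix)) {
    notify("imputing %d missing score(s) as 0", sum(is.na(s_matrix)))
    s_matrix[is.na(s_matrix)] <- 0
  }
  hc <- hclust(dist(s_matrix, method = distance), method = linkage)
  labels <- cutree(hc, k = n_clusters)
  attr(labels, "hclust") <- hc
  labels
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `p_adj[(i)] = min_{j >= i} m * p[(j)] / j`, capped at 1; order-preserving
#' (result matched back to the input positions).
#'
#' @param p numeric vector of p-values in [0, 1] (no NA).
#' @return adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  if (anyNA(p)) abort("bh_adjust does not accept NA p-values")
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

#' Hypergeometric term enrichment
#'
#' For each term with at least one universe gene: with `N` = universe size,
#' `K` = term size, `n` = query size and `k` = hits, the enrichment p-value
#' is the upper tail `P[X >= k]`, `X ~ Hypergeometric(N, K, n)`. P-values are
#' BH-adjusted across all tested terms and, by default, filtered at
#' `p_adj < cutoff`.
#'
#' @param query character vector of query genes (must be a subset of
#'   `universe`).
#' @param term2gene data.frame with columns `term_id`, `gene_id` (and
#'   optionally `term_name`).
#' @param universe character vector: the gene universe.
#' @param cutoff adjusted-p filter threshold (default 0.01).
#' @param filter keep only terms passing the cutoff (default TRUE).
#' @return data.frame with columns `term_id`, `term_name`, `k`, `n`, `K`,
#'   `N`, `gene_ratio`, `p`, `p_adj`, sorted by ascending p.
#' @export
enrich_terms <- function(query, term2gene, universe, cutoff = 0.01,
                         filter = TRUE) {
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  bad <- setdiff(query, universe)
  if (length(bad) > 0L) {
    abort("query gene(s) outside the universe: %s",
          paste(head(bad, 5L), collapse = ", "))
  }
  t2g <- unique(term2gene[term2gene$gene_id %in% universe,
                          intersect(c("term_id", "term_name", "gene_id"),
                                    names(term2gene))])
  if (nrow(t2g) == 0L) {
    return(data.frame(term_id = character(), term_name = character(),
                      k = integer(), n = integer(), K = integer(),
                      N = integer(), gene_ratio = numeric(), p = numeric(),
                      p_adj = numeric(), stringsAsFactors = FALSE))
  }
  terms <- unique(t2g$term_id)
  name_of <- if ("term_name" %in% names(t2g)) {
    stats::setNames(t2g$term_name, t2g$term_id)
  } else stats::setNames(terms, terms)
  N <- length(universe)
  n <- length(query)
  K <- as.integer(table(factor(t2g$term_id, levels = terms)))
  hits <- t2g[t2g$gene_id %in% query, ]
  k <- as.integer(table(factor(hits$term_id, levels = terms)))
  p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  out <- data.frame(term_id = terms, term_name = unname(name_of[terms]),
                    k = k, n = n, K = K, N = N, gene_ratio = k / n,
                    p = p, p_adj = bh_adjust(p), stringsAsFactors = FALSE)
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  if (filter) out[out$p_adj < cutoff, , drop = FALSE] else out
}
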