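# Over-representation analysis of co-regulatory-network members against
# annotated gene/miRNA set collections (GMT): one-sided hypergeometric test
# per set with Benjamini-Hochberg adjustment across the collection.

#' Hypergeometric over-representation analysis
#'
#' Each set is intersected with the background universe before testing. With
#' `N` the background size, `K` the (intersected) set size, `n` the query
#' size, and `k` the query/set overlap, the p-value is the hypergeometric
#' upper tail `P(X >= k)`. q-values are Benjamini-Hochberg adjusted over all
#' tested sets.
#'
#' @param query character vector of identifiers; ids outside the background
#'   are dropped.
#' @param sets named list of character vectors (e.g. from [read_gmt()]).
#' @param background character vector: the universe of testable identifiers.
#' @param case_insensitive match identifiers case-insensitively (use for
#'   miRNA collections).
#' @return data frame with one row per set: `set`, `k`, `K`, `n`, `N`, `p`,
#'   `q`, sorted by p ascending.
#' @export
enrich <- function(query, sets, background, case_insensitive = FALSE) {
  if (length(background) == 0L) stop("empty background universe")
  canon <- if (case_insensitive) tolower else identity
  background <- unique(canon(background))
  query <- unique(canon(query))
  query <- intersect(query, background)
  N <- length(background)
  n <- length(query)

  rows <- lapply(names(sets), function(nm) {
    members <- intersect(unique(canon(sets[[nm]])), background)
    K <- length(members)
    k <- length(intersect(query, members))
    ## upper tail P(X >= k) = P(X > k - 1)
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(), k = integer(), K = integer(),
               n = integer(), N = integer(), p = numeric(),
               stringsAsFactors = FALSE)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Enrichment of co-regulatory network members
#'
#' Splits the network's nodes by class and tests genes and TFs together
#' against the gene-set collection, and miRNAs (case-insensitively) against
#' the miRNA-set collection. The default background is all identifiers of the
#' matching class in `background_network` (typically the assembled,
#' pre-screening network); it may be overridden with explicit vectors.
#'
#' @param network the co-regulatory `"typed_network"` whose members to test.
#' @param gene_sets,mirna_sets named lists of sets (either may be `NULL`).
#' @param background_network a `"typed_network"` defining the default
#'   background universes.
#' @param gene_background,mirna_background optional explicit universes.
#' @return list with elements `genes` and `mirnas`, each an [enrich()] table
#'   (or `NULL` where no collection was supplied).
#' @export
enrich_network <- function(network, gene_sets = NULL, mirna_sets = NULL,
                           background_network = network,
                           gene_background = NULL, mirna_background = NULL) {
  nodes <- network$nodes
  bg <- background_network$nodes
  res <- list(genes = NULL, mirnas = NULL)
  if (!is.null(gene_sets)) {
    if (is.null(gene_background)) {
      gene_background <- bg$id[bg$node_class %in% c("GENE", "TF")]
    }
    res$genes <- enrich(nodes$id[nodes$node_class %in% c("GENE", "TF")],
                        gene_sets, gene_background)
  }
  if (!is.null(mirna_sets)) {
    if (is.null(mirna_background)) {
      mirna_background <- bg$id[bg$node_class == "MIRNA"]
    }
    res$mirnas <- enrich(nodes$id[nodes$node_class == "MIRNA"],
                         mirna_sets, mirna_background, case_insensitive = TRUE)
  }
  res
}
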