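# Pooling the four regulatory edge tables into one typed network,
# evidence-level filtering, and screening to cancer-relevant interactions.

#' Assemble a typed network from regulatory edge tables
#'
#' Pools any subset of the four interaction kinds into one directed network.
#' Under `"VALIDATED"` mode only edges whose evidence set contains VALIDATED
#' are kept; `"PREDICTED"` keeps edges containing PREDICTED; `"BOTH"` keeps
#' all edges. Node classes are resolved from the interaction kinds, with
#' TF-over-gene promotion: an identifier seen both as a TF and as a gene
#' target is a TF everywhere (TFs are genes). An identifier required to be
#' both a miRNA and a TF/gene is an error. Nodes without a surviving incident
#' edge are dropped.
#'
#' @param tables a list of [edge_table()]s (any subset of the four kinds).
#' @param evidence_mode `"VALIDATED"`, `"PREDICTED"`, or `"BOTH"`.
#' @param cancer free-text label stored in the network metadata.
#' @return a `"typed_network"`.
#' @export
assemble <- function(tables, evidence_mode = c("BOTH", "VALIDATED", "PREDICTED"),
                     cancer = NA_character_) {
  evidence_mode <- match.arg(toupper(evidence_mode[1]),
                             c("BOTH", "VALIDATED", "PREDICTED"))
  if (inherits(tables, "edge_table")) tables <- list(tables)
  edges <- do.call(rbind, c(lapply(tables, as.data.frame), list(empty_edges())))
  if (nrow(edges) && evidence_mode != "BOTH") {
    edges <- edges[evidence_has(edges$evidence, evidence_mode), , drop = FALSE]
  }
  typed_network(edges, metadata = list(cancer = cancer,
                                       evidence_mode = evidence_mode))
}

#' Screen a network to cancer-relevant interactions
#'
#' Retains exactly the edges with at least one endpoint in the union of the
#' cancer gene and cancer miRNA lists (or both endpoints with
#' `strict = TRUE`), then drops newly isolated nodes. miRNA-class nodes are
#' matched case-insensitively against the lists.
#'
#' @param network a `"typed_network"`.
#' @param cancer_genes,cancer_mirnas character vectors of identifiers.
#' @param strict if `TRUE`, require both endpoints in the cancer set.
#' @return the screened `"typed_network"` (a subgraph of the input).
#' @export
screen_cancer <- function(network, cancer_genes = character(),
                          cancer_mirnas = character(), strict = FALSE) {
  cancer <- unique(c(cancer_genes, cancer_mirnas))
  if (length(cancer) == 0L) {
    warning("both cancer lists empty; screened network is empty")
    return(typed_network(metadata = network$metadata))
  }
  if (nrow(network$edges) == 0L) return(network)
  lower <- tolower(cancer)
  in_set <- function(ids, classes) {
    ids %in% cancer | (classes == "MIRNA" & tolower(ids) %in% lower)
  }
  cls <- stats::setNames(network$nodes$node_class, network$nodes$id)
  s_in <- in_set(network$edges$source, cls[network$edges$source])
  t_in <- in_set(network$edges$target, cls[network$edges$target])
  keep <- if (strict) s_in & t_in else s_in | t_in
  typed_network(network$edges[keep, , drop = FALSE],
                metadata = network$metadata)
}
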