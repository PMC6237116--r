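# Enumeration and classification of miRNA-TF co-regulatory motifs:
# co-regulatory pairs and the three classes of three-node feed-forward loops.
#
# A triad (TF, miRNA, target) qualifies when both joint-target edges
# (TF -> target and miRNA -> target) are present. The regulator-regulator
# edges then decide the class:
#   neither TF->miRNA nor miRNA->TF : co-regulatory pair
#   TF->miRNA only                  : TF-FFL   (TF is the master regulator)
#   miRNA->TF only                  : miRNA-FFL (miRNA is the master regulator)
#   both                            : composite-FFL (mutual regulation)
# Classes are mutually exclusive, so motif counts partition the triads.

#' Classify a single (TF, miRNA, target) triad
#'
#' @param tf,mirna,target node identifiers; the three must be pairwise
#'   distinct and carry the required classes in `network`.
#' @param network a `"typed_network"`.
#' @return one of `"COREG_PAIR"`, `"TF_FFL"`, `"MIRNA_FFL"`,
#'   `"COMPOSITE_FFL"`, or `NA_character_` when either joint-target edge is
#'   missing.
#' @export
classify_triad <- function(tf, mirna, target, network) {
  cls <- stats::setNames(network$nodes$node_class, network$nodes$id)
  if (is.na(cls[tf]) || cls[[tf]] != "TF") stop("not a TF node: ", tf)
  if (is.na(cls[mirna]) || cls[[mirna]] != "MIRNA") {
    stop("not a miRNA node: ", mirna)
  }
  if (is.na(cls[target]) || !cls[[target]] %in% c("GENE", "TF")) {
    stop("not a target (gene/TF) node: ", target)
  }
  if (length(unique(c(tf, mirna, target))) != 3L) {
    stop("triad nodes must be pairwise distinct")
  }
  keys <- edge_pair_keys(network$edges)
  has <- function(a, b) paste(a, b, sep = "\r") %in% keys
  if (!has(tf, target) || !has(mirna, target)) return(NA_character_)
  t2m <- has(tf, mirna)
  m2t <- has(mirna, tf)
  if (t2m && m2t) "COMPOSITE_FFL"
  else if (t2m) "TF_FFL"
  else if (m2t) "MIRNA_FFL"
  else "COREG_PAIR"
}

#' Enumerate all co-regulatory pairs and FFLs in a network
#'
#' Exhaustively lists every (TF, miRNA, target) triad in which both
#' joint-target edges are present, classified as in [classify_triad()]. Output
#' is deterministic: rows sorted by (tf, mirna, target).
#'
#' @param network a `"typed_network"`.
#' @param allow_tf_targets if `TRUE`, a TF distinct from the regulator TF may
#'   itself be the joint target; by default targets are GENE-class nodes only.
#' @param pairs_include_ffl_triads if `TRUE`, FFL triads are additionally
#'   reported as co-regulatory pairs (inclusive counting); by default the four
#'   classes are mutually exclusive.
#' @return a data frame of class `"motif_table"` with columns `motif_class`,
#'   `tf`, `mirna`, `target`.
#' @export
enumerate_motifs <- function(network, allow_tf_targets = FALSE,
                             pairs_include_ffl_triads = FALSE) {
  edges <- network$edges
  out <- list()
  if (nrow(edges)) {
    cls <- stats::setNames(network$nodes$node_class, network$nodes$id)
    keys <- edge_pair_keys(edges)
    tf_tgt <- edges[edges$interaction_kind == "TF_GENE", , drop = FALSE]
    mir_tgt <- edges[edges$interaction_kind %in%
                       c("MIRNA_GENE", "MIRNA_TF"), , drop = FALSE]
    targets <- intersect(unique(tf_tgt$target), unique(mir_tgt$target))
    if (!allow_tf_targets) targets <- targets[cls[targets] == "GENE"]
    for (g in targets) {
      tfs <- tf_tgt$source[tf_tgt$target == g]
      tfs <- setdiff(tfs, g)
      mirs <- mir_tgt$source[mir_tgt$target == g]
      if (!length(tfs) || !length(mirs)) next
      grid <- expand.grid(tf = tfs, mirna = mirs, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
      t2m <- paste(grid$tf, grid$mirna, sep = "\r") %in% keys
      m2t <- paste(grid$mirna, grid$tf, sep = "\r") %in% keys
      grid$motif_class <- ifelse(t2m & m2t, "COMPOSITE_FFL",
                          ifelse(t2m, "TF_FFL",
                          ifelse(m2t, "MIRNA_FFL", "COREG_PAIR")))
      grid$target <- g
      out[[length(out) + 1L]] <- grid
      if (pairs_include_ffl_triads && any(t2m | m2t)) {
        extra <- grid[t2m | m2t, , drop = FALSE]
        extra$motif_class <- "COREG_PAIR"
        out[[length(out) + 1L]] <- extra
      }
    }
  }
  motifs <- if (length(out)) do.call(rbind, out) else
    data.frame(tf = character(), mirna = character(),
               motif_class = character(), target = character(),
               stringsAsFactors = FALSE)
  motifs <- motifs[, c("motif_class", "tf", "mirna", "target")]
  motifs <- motifs[order(motifs$tf, motifs$mirna, motifs$target), ,
                   drop = FALSE]
  rownames(motifs) <- NULL
  class(motifs) <- c("motif_table", "data.frame")
  motifs
}

#' Restrict motifs to those touching a query list
#'
#' Keeps motifs with at least one member node (TF, miRNA, or target) in the
#' query; miRNA members are matched case-insensitively.
#'
#' @param motifs a `"motif_table"`.
#' @param query character vector of identifiers.
#' @return the filtered `"motif_table"`.
#' @export
restrict_to_query <- function(motifs, query) {
  if (length(query) == 0L) {
    warning("empty query; no motifs retained")
    return(motifs[0, , drop = FALSE])
  }
  lower <- tolower(query)
  keep <- motifs$tf %in% query | motifs$target %in% query |
    motifs$mirna %in% query | tolower(motifs$mirna) %in% lower
  motifs[keep, , drop = FALSE]
}

#' Member edges of each motif
#'
#' Every motif contributes its two joint-target edges; FFLs add the
#' regulator-regulator edge(s): TF->miRNA for a TF-FFL, miRNA->TF for a
#' miRNA-FFL, both for a composite-FFL.
#'
#' @param motifs a `"motif_table"`.
#' @return a data frame with columns `motif_idx` (row of `motifs`), `source`,
#'   `target`, `role` (one of `tf_target`, `mirna_target`, `tf_mirna`,
#'   `mirna_tf`), and `mirna_source` (logical: does the miRNA regulate here).
#' @export
motif_member_edges <- function(motifs) {
  n <- nrow(motifs)
  if (n == 0L) {
    return(data.frame(motif_idx = integer(), source = character(),
                      target = character(), role = character(),
                      mirna_source = logical(), stringsAsFactors = FALSE))
  }
  base <- data.frame(
    motif_idx = rep(seq_len(n), 2L),
    source = c(motifs$tf, motifs$mirna),
    target = rep(motifs$target, 2L),
    role = rep(c("tf_target", "mirna_target"), each = n),
    mirna_source = rep(c(FALSE, TRUE), each = n),
    stringsAsFactors = FALSE)
  t2m <- which(motifs$motif_class %in% c("TF_FFL", "COMPOSITE_FFL"))
  m2t <- which(motifs$motif_class %in% c("MIRNA_FFL", "COMPOSITE_FFL"))
  extra <- rbind(
    if (length(t2m)) data.frame(motif_idx = t2m, source = motifs$tf[t2m],
                                target = motifs$mirna[t2m], role = "tf_mirna",
                                mirna_source = FALSE, stringsAsFactors = FALSE),
    if (length(m2t)) data.frame(motif_idx = m2t, source = motifs$mirna[m2t],
                                target = motifs$tf[m2t], role = "mirna_tf",
                                mirna_source = TRUE, stringsAsFactors = FALSE))
  out <- rbind(base, extra)
  out[order(out$motif_idx, out$role), , drop = FALSE]
}

#' Build the co-regulatory network from a motif collection
#'
#' The union of all member nodes and member edges of the motifs, as a typed
#' network. Member edges are looked up in the source network so that evidence
#' and provenance attributes are preserved.
#'
#' @param motifs a `"motif_table"`.
#' @param network the `"typed_network"` the motifs were enumerated from.
#' @return a `"typed_network"` containing exactly the motif members.
#' @export
build_coreg_network <- function(motifs, network) {
  mem <- motif_member_edges(motifs)
  if (nrow(mem) == 0L) return(typed_network(metadata = network$metadata))
  want <- unique(paste(mem$source, mem$target, sep = "\r"))
  keep <- edge_pair_keys(network$edges) %in% want
  typed_network(network$edges[keep, , drop = FALSE],
                metadata = network$metadata)
}

#' Tabulate motif counts per class
#' @param motifs a `"motif_table"`.
#' @return named integer vector over the four motif classes.
#' @export
motif_class_counts <- function(motifs) {
  tab <- table(factor(motifs$motif_class, levels = MOTIF_CLASSES))
  stats::setNames(as.integer(tab), MOTIF_CLASSES)
}
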