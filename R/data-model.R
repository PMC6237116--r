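# Domain types: node classes, interaction kinds, evidence levels, edge tables
# and the typed network container used throughout the pipeline.

NODE_CLASSES <- c("TF", "MIRNA", "GENE")
INTERACTION_KINDS <- c("TF_GENE", "TF_MIRNA", "MIRNA_GENE", "MIRNA_TF")
EVIDENCE_LEVELS <- c("VALIDATED", "PREDICTED")
MOTIF_CLASSES <- c("COREG_PAIR", "TF_FFL", "MIRNA_FFL", "COMPOSITE_FFL")

# Node class implied by each interaction kind for its source / target endpoint.
KIND_SOURCE_CLASS <- c(TF_GENE = "TF", TF_MIRNA = "TF",
                       MIRNA_GENE = "MIRNA", MIRNA_TF = "MIRNA")
KIND_TARGET_CLASS <- c(TF_GENE = "GENE", TF_MIRNA = "MIRNA",
                       MIRNA_GENE = "GENE", MIRNA_TF = "TF")

#' Canonical comparison key for a node identifier
#'
#' Gene and TF symbols are compared case-sensitively; miRNA names are compared
#' case-insensitively because capitalisation conventions vary
#' ("hsa-mir-25" vs "hsa-miR-25").
#'
#' @param id character vector of identifiers.
#' @param node_class character vector (recycled) of classes in
#'   `c("TF", "MIRNA", "GENE")`.
#' @return character vector of comparison keys.
#' @keywords internal
node_key <- function(id, node_class) {
  node_class <- rep_len(node_class, length(id))
  out <- id
  mir <- node_class == "MIRNA"
  out[mir] <- tolower(id[mir])
  out
}

## Evidence sets are stored as a single string of sorted, comma-joined levels,
## e.g. "VALIDATED" or "PREDICTED,VALIDATED".
evidence_string <- function(levels_list) {
  vapply(levels_list,
         function(ev) paste(sort(unique(ev)), collapse = ","),
         character(1))
}

evidence_union <- function(a, b) {
  vapply(seq_along(a), function(i) {
    paste(sort(unique(c(strsplit(a[i], ",", fixed = TRUE)[[1]],
                        strsplit(b[i], ",", fixed = TRUE)[[1]]))),
          collapse = ",")
  }, character(1))
}

evidence_has <- function(evidence, level) {
  vapply(strsplit(evidence, ",", fixed = TRUE),
         function(ev) level %in% ev, logical(1))
}

normalize_evidence <- function(x) {
  up <- toupper(trimws(x))
  up[up %in% EVIDENCE_LEVELS]  # callers handle length drop
}

#' Construct an edge table
#'
#' An edge table is a data frame of regulatory edges that all share one
#' interaction kind. Duplicate (source, target) rows are merged and their
#' evidence sets unioned; miRNA endpoints are deduplicated case-insensitively,
#' keeping the first spelling seen. Self-loops are rejected.
#'
#' @param source,target character vectors of regulator and target identifiers.
#' @param interaction_kind one of `"TF_GENE"`, `"TF_MIRNA"`, `"MIRNA_GENE"`,
#'   `"MIRNA_TF"`.
#' @param evidence character vector (recycled): comma-joined subsets of
#'   `"VALIDATED"`/`"PREDICTED"`.
#' @param provenance free-text source label, recycled.
#' @return a data frame of class `"edge_table"` with columns `source`,
#'   `target`, `interaction_kind`, `evidence`, `provenance` and a
#'   `"load_report"` attribute.
#' @export
edge_table <- function(source = character(), target = character(),
                       interaction_kind, evidence = "VALIDATED",
                       provenance = "user") {
  interaction_kind <- match.arg(interaction_kind, INTERACTION_KINDS)
  stopifnot(length(source) == length(target))
  n <- length(source)
  source <- trimws(source)
  target <- trimws(target)
  evidence <- rep_len(evidence, n)
  provenance <- rep_len(provenance, n)

  keep <- nzchar(source) & nzchar(target) &
    node_key(source, KIND_SOURCE_CLASS[interaction_kind]) !=
      node_key(target, KIND_TARGET_CLASS[interaction_kind])
  df <- data.frame(source = source[keep], target = target[keep],
                   interaction_kind = rep_len(interaction_kind, sum(keep)),
                   evidence = evidence[keep], provenance = provenance[keep],
                   stringsAsFactors = FALSE)
  df <- merge_duplicate_edges(df)
  structure(df,
            class = c("edge_table", "data.frame"),
            interaction_kind = interaction_kind,
            load_report = list(rows_in = n, rows_kept = nrow(df),
                               skipped = n - sum(keep)))
}

## Merge duplicate (source, target) rows within one kind, unioning evidence.
## miRNA endpoints compared case-insensitively; the first-seen spelling wins.
merge_duplicate_edges <- function(df) {
  if (nrow(df) == 0L) return(df)
  kind <- df$interaction_kind
  key <- paste(node_key(df$source, KIND_SOURCE_CLASS[kind]),
               node_key(df$target, KIND_TARGET_CLASS[kind]),
               kind, sep = "\r")
  first <- !duplicated(key)
  idx <- match(key, key[first])
  ev <- df$evidence[first]
  dup <- which(!first)
  for (i in dup) {
    j <- idx[i]
    ev[j] <- evidence_union(ev[j], df$evidence[i])
  }
  out <- df[first, , drop = FALSE]
  out$evidence <- ev
  rownames(out) <- NULL
  out
}

#' Construct a typed regulatory network
#'
#' @param edges data frame with columns `source`, `target`,
#'   `interaction_kind`, `evidence`, `provenance`.
#' @param metadata named list (e.g. cancer label, evidence mode).
#' @return object of class `"typed_network"`: a list with elements `nodes`
#'   (data frame `id`, `node_class`), `edges`, and `metadata`. Node classes
#'   are derived from the interaction kinds and are globally consistent; an
#'   identifier required to be both a miRNA and a gene/TF is an error.
#' @export
typed_network <- function(edges = empty_edges(), metadata = list()) {
  ## plain data frame: drop edge_table class and bookkeeping attributes
  edges <- data.frame(source = edges$source, target = edges$target,
                      interaction_kind = edges$interaction_kind,
                      evidence = edges$evidence,
                      provenance = edges$provenance,
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0L) {
    return(structure(list(nodes = data.frame(id = character(),
                                             node_class = character(),
                                             stringsAsFactors = FALSE),
                          edges = empty_edges(), metadata = metadata),
                     class = "typed_network"))
  }
  stopifnot(all(edges$interaction_kind %in% INTERACTION_KINDS))

  ## canonicalise miRNA spellings network-wide: first-seen spelling per
  ## lower-cased name
  mir_src <- edges$interaction_kind %in% c("MIRNA_GENE", "MIRNA_TF")
  mir_tgt <- edges$interaction_kind == "TF_MIRNA"
  mir_ids <- c(edges$source[mir_src], edges$target[mir_tgt])
  if (length(mir_ids)) {
    canon <- mir_ids[!duplicated(tolower(mir_ids))]
    names(canon) <- tolower(canon)
    edges$source[mir_src] <- unname(canon[tolower(edges$source[mir_src])])
    edges$target[mir_tgt] <- unname(canon[tolower(edges$target[mir_tgt])])
  }

  edges <- merge_duplicate_edges(edges)

  ## resolve node classes with TF-over-GENE promotion
  ids <- c(edges$source, edges$target)
  cls <- c(KIND_SOURCE_CLASS[edges$interaction_kind],
           KIND_TARGET_CLASS[edges$interaction_kind])
  tf_ids <- unique(ids[cls == "TF"])
  mir_ids <- unique(ids[cls == "MIRNA"])
  gene_ids <- unique(ids[cls == "GENE"])
  conflict <- intersect(tolower(mir_ids), tolower(c(tf_ids, gene_ids)))
  if (length(conflict)) {
    stop("identifier(s) required to be both miRNA and TF/gene: ",
         paste(utils::head(conflict, 5), collapse = ", "))
  }
  gene_ids <- setdiff(gene_ids, tf_ids)  # TFs are genes; TF class wins
  nodes <- data.frame(
    id = c(tf_ids, mir_ids, gene_ids),
    node_class = rep(c("TF", "MIRNA", "GENE"),
                     c(length(tf_ids), length(mir_ids), length(gene_ids))),
    stringsAsFactors = FALSE)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- edges[order(edges$source, edges$target, edges$interaction_kind), ,
                 drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, metadata = metadata),
            class = "typed_network")
}

empty_edges <- function() {
  data.frame(source = character(), target = character(),
             interaction_kind = character(), evidence = character(),
             provenance = character(), stringsAsFactors = FALSE)
}

#' @export
print.typed_network <- function(x, ...) {
  cat("Typed regulatory network\n")
  tab <- table(factor(x$nodes$node_class, levels = NODE_CLASSES))
  cat(sprintf("  nodes: %d (TF %d, miRNA %d, gene %d)\n", nrow(x$nodes),
              tab[["TF"]], tab[["MIRNA"]], tab[["GENE"]]))
  cat(sprintf("  edges: %d\n", nrow(x$edges)))
  if (nrow(x$edges)) {
    kt <- table(factor(x$edges$interaction_kind, levels = INTERACTION_KINDS))
    cat("  ", paste(names(kt), kt, sep = "=", collapse = "  "), "\n")
  }
  if (length(x$metadata)) {
    cat("  metadata:", paste(names(x$metadata),
                             vapply(x$metadata, function(v)
                               paste(format(v), collapse = ","), ""),
                             sep = "=", collapse = "  "), "\n")
  }
  invisible(x)
}

## Internal: fast membership set of "source\rtarget" pairs
edge_pair_keys <- function(edges) {
  paste(edges$source, edges$target, sep = "\r")
}
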