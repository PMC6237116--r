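# Readers and writers for the external formats the pipeline touches:
# TSV edge tables, plain-text node lists, GMT gene-set collections,
# expression matrices, and GraphML/JSON network export.

#' Read a regulatory edge table from TSV
#'
#' The file has no header and at least two tab-separated columns: regulator
#' identifier and target identifier. An optional third column overrides the
#' table-level evidence per row with `"validated"`, `"predicted"`, or a
#' comma-joined subset of the two
#' (case-insensitive); rows with any other evidence string, fewer than two
#' fields, empty identifiers, or a self-loop are skipped and counted in the
#' load report.
#'
#' @param path path to the TSV file.
#' @param interaction_kind one of `"TF_GENE"`, `"TF_MIRNA"`, `"MIRNA_GENE"`,
#'   `"MIRNA_TF"`.
#' @param evidence table-level evidence tag, `"VALIDATED"` or `"PREDICTED"`.
#' @param provenance free-text source label stored on every edge.
#' @return an [edge_table()] with duplicates merged; the `"load_report"`
#'   attribute counts rows read, kept, and skipped.
#' @export
read_edge_table <- function(path, interaction_kind,
                            evidence = "VALIDATED", provenance = NULL) {
  interaction_kind <- match.arg(interaction_kind, INTERACTION_KINDS)
  if (!file.exists(path)) stop("edge table file not found: ", path)
  evidence <- toupper(evidence)
  stopifnot(evidence %in% EVIDENCE_LEVELS)
  if (is.null(provenance)) provenance <- basename(path)

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  n_in <- length(lines)
  if (n_in == 0L) {
    warning("no parseable rows in ", path)
    tab <- edge_table(interaction_kind = interaction_kind)
    attr(tab, "load_report") <- list(rows_in = 0L, rows_kept = 0L, skipped = 0L)
    return(tab)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  src <- vapply(fields, function(f) if (length(f) >= 1) trimws(f[1]) else "", "")
  tgt <- vapply(fields, function(f) if (length(f) >= 2) trimws(f[2]) else "", "")
  ev_raw <- vapply(fields, function(f) if (length(f) >= 3) trimws(f[3]) else "", "")
  ev <- rep(evidence, n_in)
  has_ev <- nzchar(ev_raw)
  ## a row may carry one level or a comma-joined subset ("validated,predicted")
  ev_parts <- lapply(strsplit(toupper(ev_raw[has_ev]), ",", fixed = TRUE),
                     trimws)
  ev_ok_parts <- vapply(ev_parts,
                        function(p) length(p) > 0 && all(p %in% EVIDENCE_LEVELS),
                        logical(1))
  ev[has_ev] <- vapply(ev_parts,
                       function(p) paste(sort(unique(p)), collapse = ","), "")
  ev_valid <- rep(TRUE, n_in)
  ev_valid[has_ev] <- ev_ok_parts

  ok <- nzchar(src) & nzchar(tgt) & ev_valid &
    node_key(src, KIND_SOURCE_CLASS[interaction_kind]) !=
      node_key(tgt, KIND_TARGET_CLASS[interaction_kind])
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    warning(n_skipped, " malformed row(s) skipped in ", path)
  }
  tab <- edge_table(src[ok], tgt[ok], interaction_kind = interaction_kind,
                    evidence = ev[ok], provenance = provenance)
  attr(tab, "load_report") <- list(rows_in = n_in, rows_kept = nrow(tab),
                                   skipped = n_skipped)
  if (nrow(tab) == 0L) warning("zero parseable edges in ", path)
  tab
}

#' Read a node list (one identifier per line)
#'
#' Lines are trimmed, blank lines dropped, and duplicates removed.
#'
#' @param path path to a plain-text file.
#' @return character vector of unique identifiers, in first-seen order.
#' @export
read_node_list <- function(path) {
  if (!file.exists(path)) stop("node list file not found: ", path)
  ids <- trimws(readLines(path, warn = FALSE))
  ids <- unique(ids[nzchar(ids)])
  if (length(ids) == 0L) warning("empty node list: ", path)
  ids
}

#' Write a node list, one identifier per line
#' @param ids character vector.
#' @param path output path.
#' @export
write_node_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: each line is `name<TAB>description<TAB>member1<TAB>member2...`.
#' Lines with fewer than three fields are skipped with a warning; duplicate
#' set names are an error; members are deduplicated within a set.
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (the sets), with a `"descriptions"`
#'   attribute (named character vector).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, 0L) < 3L
  if (any(short)) {
    warning(sum(short), " GMT line(s) with <3 fields skipped in ", path)
    fields <- fields[!short]
  }
  if (length(fields) == 0L) {
    out <- list()
    attr(out, "descriptions") <- character()
    return(out)
  }
  nm <- vapply(fields, `[`, "", 1L)
  if (anyDuplicated(nm)) {
    stop("duplicate gene-set name(s) in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(trimws(f[-(1:2)])))
  sets <- lapply(sets, function(s) s[nzchar(s)])
  names(sets) <- nm
  desc <- vapply(fields, `[`, "", 2L)
  names(desc) <- nm
  attr(sets, "descriptions") <- desc
  sets
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "descriptions")
  if (is.null(desc)) desc <- setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read matched gene and miRNA expression matrices
#'
#' Each TSV has a header row of sample identifiers and one feature per row
#' (first column the feature identifier). Sample columns are intersected and
#' put in identical order in both matrices; features whose values are all
#' missing are dropped; non-numeric cells become `NA` and are counted.
#'
#' @param gene_path path to the gene/TF expression TSV.
#' @param mirna_path path to the miRNA expression TSV.
#' @return an object of class `"expression_bundle"`: list with numeric
#'   matrices `gene` and `mirna` (features x samples, identical column order),
#'   `samples`, and `n_nonnumeric` (count of coerced cells).
#' @export
read_expression <- function(gene_path, mirna_path) {
  g <- read_expr_matrix(gene_path)
  m <- read_expr_matrix(mirna_path)
  shared <- intersect(colnames(g$mat), colnames(m$mat))
  if (length(shared) == 0L) {
    stop("no shared samples between ", gene_path, " and ", mirna_path)
  }
  expression_bundle(g$mat[, shared, drop = FALSE],
                    m$mat[, shared, drop = FALSE],
                    n_nonnumeric = g$n_bad + m$n_bad)
}

#' Assemble an expression bundle from in-memory matrices
#'
#' @param gene,mirna numeric matrices (features x samples) with row and
#'   column names; columns are intersected and aligned.
#' @param n_nonnumeric count of non-numeric cells coerced to `NA` (bookkeeping).
#' @return an `"expression_bundle"` (see [read_expression()]).
#' @export
expression_bundle <- function(gene, mirna, n_nonnumeric = 0L) {
  shared <- intersect(colnames(gene), colnames(mirna))
  if (length(shared) == 0L) stop("no shared samples")
  stopifnot(!anyDuplicated(shared),
            !anyDuplicated(rownames(gene)), !anyDuplicated(rownames(mirna)))
  gene <- gene[, shared, drop = FALSE]
  mirna <- mirna[, shared, drop = FALSE]
  gene <- gene[rowSums(!is.na(gene)) > 0L, , drop = FALSE]
  mirna <- mirna[rowSums(!is.na(mirna)) > 0L, , drop = FALSE]
  structure(list(gene = gene, mirna = mirna, samples = shared,
                 n_nonnumeric = n_nonnumeric),
            class = "expression_bundle")
}

read_expr_matrix <- function(path) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE, colClasses = "character")
  ids <- trimws(df[[1]])
  if (anyDuplicated(ids)) stop("duplicate feature ids in ", path)
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  n_bad <- sum(is.na(num) & !is.na(vals) & nzchar(trimws(vals)) &
                 toupper(trimws(vals)) != "NA")
  list(mat = num, n_bad = n_bad)
}

#' Write an expression matrix as TSV
#' @param mat numeric matrix with row and column names.
#' @param path output path.
#' @export
write_expr_matrix <- function(mat, path) {
  df <- data.frame(feature = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export a typed network to GraphML or JSON
#'
#' GraphML carries the node attribute `node_class` and edge attributes
#' `interaction_kind` and `evidence` (and `provenance`); the JSON form is a
#' `{"nodes": [...], "links": [...]}` document suitable for force-directed
#' renderers. Both round-trip through [read_network()].
#'
#' @param network a `"typed_network"`.
#' @param path output path.
#' @param format `"GRAPHML"` or `"JSON"` (case-insensitive).
#' @export
write_network <- function(network, path, format = c("GRAPHML", "JSON")) {
  format <- toupper(format)
  format <- match.arg(format)
  if (format == "GRAPHML") {
    g <- network_to_igraph(network)
    igraph::write_graph(g, path, format = "graphml")
  } else {
    doc <- list(
      nodes = data.frame(id = network$nodes$id,
                         node_class = network$nodes$node_class,
                         stringsAsFactors = FALSE),
      links = data.frame(source = network$edges$source,
                         target = network$edges$target,
                         interaction_kind = network$edges$interaction_kind,
                         evidence = network$edges$evidence,
                         provenance = network$edges$provenance,
                         stringsAsFactors = FALSE))
    jsonlite::write_json(doc, path, dataframe = "rows", auto_unbox = TRUE,
                         pretty = TRUE)
  }
  invisible(path)
}

#' Read a typed network written by [write_network()]
#'
#' @param path path to a GraphML or JSON file.
#' @param format `"GRAPHML"` or `"JSON"`; default guessed from the extension.
#' @return a `"typed_network"`.
#' @export
read_network <- function(path, format = NULL) {
  if (!file.exists(path)) stop("network file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "JSON"
              else "GRAPHML"
  }
  format <- match.arg(toupper(format), c("GRAPHML", "JSON"))
  if (format == "GRAPHML") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::ecount(g) == 0L) {
      edges <- empty_edges()
    } else {
      el <- igraph::as_edgelist(g, names = TRUE)
      edges <- data.frame(
        source = el[, 1], target = el[, 2],
        interaction_kind = igraph::edge_attr(g, "interaction_kind"),
        evidence = igraph::edge_attr(g, "evidence"),
        provenance = igraph::edge_attr(g, "provenance"),
        stringsAsFactors = FALSE)
    }
  } else {
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    edges <- as.data.frame(doc$links, stringsAsFactors = FALSE)
    if (nrow(edges) == 0L) edges <- empty_edges()
  }
  typed_network(edges)
}

network_to_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = network$edges[, c("source", "target", "interaction_kind",
                          "evidence", "provenance")],
    directed = TRUE,
    vertices = data.frame(name = network$nodes$id,
                          node_class = network$nodes$node_class,
                          stringsAsFactors = FALSE))
}
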