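# End-to-end pipeline: assemble -> screen -> enumerate motifs ->
# (subgraph restriction) -> expression refinement -> co-regulatory network ->
# topology scores, motif ranking, enrichment -> result bundle on disk.

#' Run configuration
#'
#' @param tf_gene,tf_mirna,mirna_gene,mirna_tf paths to the four edge-table
#'   TSVs (any may be `NULL` to omit that kind).
#' @param cancer_genes,cancer_mirnas paths to cancer node lists (`NULL` skips
#'   cancer screening).
#' @param gene_expression,mirna_expression paths to expression TSVs (`NULL`
#'   skips refinement).
#' @param gene_sets,mirna_sets paths to GMT files (`NULL` skips that
#'   enrichment).
#' @param evidence `"validated"`, `"predicted"`, or `"both"`.
#' @param mode `"full"` or `"subgraph"`; subgraph mode requires `query`.
#' @param query path to a query node list (subgraph mode).
#' @param alpha,coeff_cutoff,tf_sign,drop_unmeasured refinement policy, see
#'   [filter_policy()].
#' @param pairs_include_ffl_triads,allow_tf_targets see [enumerate_motifs()].
#' @param cancer free-text cancer label for reports.
#' @param seed integer seed recorded in the summary.
#' @param out output directory.
#' @return a validated list of class `"run_config"`.
#' @export
run_config <- function(tf_gene = NULL, tf_mirna = NULL, mirna_gene = NULL,
                       mirna_tf = NULL, cancer_genes = NULL,
                       cancer_mirnas = NULL, gene_expression = NULL,
                       mirna_expression = NULL, gene_sets = NULL,
                       mirna_sets = NULL, evidence = "both", mode = "full",
                       query = NULL, alpha = 0.05, coeff_cutoff = 0.2,
                       tf_sign = "both", drop_unmeasured = TRUE,
                       pairs_include_ffl_triads = FALSE,
                       allow_tf_targets = FALSE, cancer = NA_character_,
                       seed = 1L, out = "mirtfnet_out") {
  mode <- match.arg(tolower(mode), c("full", "subgraph"))
  evidence <- match.arg(tolower(evidence), c("both", "validated", "predicted"))
  if (mode == "subgraph" && is.null(query)) {
    stop("subgraph mode requires a query node list")
  }
  paths <- list(tf_gene = tf_gene, tf_mirna = tf_mirna,
                mirna_gene = mirna_gene, mirna_tf = mirna_tf,
                cancer_genes = cancer_genes, cancer_mirnas = cancer_mirnas,
                gene_expression = gene_expression,
                mirna_expression = mirna_expression,
                gene_sets = gene_sets, mirna_sets = mirna_sets, query = query)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p)) {
      stop("configured path for '", nm, "' does not exist: ", p)
    }
  }
  structure(c(paths,
              list(evidence = toupper(evidence), mode = toupper(mode),
                   policy = filter_policy(alpha, coeff_cutoff, tf_sign,
                                          drop_unmeasured),
                   pairs_include_ffl_triads = isTRUE(pairs_include_ffl_triads),
                   allow_tf_targets = isTRUE(allow_tf_targets),
                   cancer = cancer, seed = as.integer(seed), out = out)),
            class = "run_config")
}

#' Load a run configuration from a YAML file
#'
#' Top-level YAML keys mirror the arguments of [run_config()]; `overrides`
#' (a named list, e.g. from command-line flags) take precedence. Relative
#' paths are resolved against the YAML file's directory.
#'
#' @param path YAML file.
#' @param overrides named list of [run_config()] arguments.
#' @return a `"run_config"`.
#' @export
load_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  path_keys <- c("tf_gene", "tf_mirna", "mirna_gene", "mirna_tf",
                 "cancer_genes", "cancer_mirnas", "gene_expression",
                 "mirna_expression", "gene_sets", "mirna_sets", "query")
  base <- dirname(normalizePath(path))
  for (k in intersect(path_keys, names(cfg))) {
    if (!is.null(cfg[[k]]) && !grepl("^(/|[A-Za-z]:)", cfg[[k]])) {
      cfg[[k]] <- file.path(base, cfg[[k]])
    }
  }
  cfg[names(overrides)] <- overrides
  do.call(run_config, cfg)
}

#' Run the co-regulatory network pipeline
#'
#' Executes the staged pipeline and writes a result bundle to `config$out`:
#' motif tables (TSV, with per-edge rho/p when refined), the co-regulatory
#' network (GraphML + JSON), topology score and motif-ranking tables,
#' enrichment tables, and `summary.json` with per-class motif counts before
#' and after refinement.
#'
#' @param config a [run_config()].
#' @param through last stage to run: `"build"` (network + motifs),
#'   `"refine"`, `"topology"`, or `"enrich"` (everything; default). Stages
#'   whose inputs are not configured are skipped.
#' @return invisibly, a list with the in-memory results (`network`,
#'   `screened`, `motifs`, `refined`, `coreg`, `topology`, `ranking`,
#'   `enrichment`, `summary`).
#' @export
run_pipeline <- function(config, through = c("enrich", "topology", "refine",
                                             "build")) {
  stopifnot(inherits(config, "run_config"))
  through <- match.arg(through)
  stage_rank <- c(build = 1, refine = 2, topology = 3, enrich = 4)
  want <- function(stage) stage_rank[[stage]] <= stage_rank[[through]]
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)

  log_msg <- function(...) message("[mirtfnet] ", sprintf(...))

  ## -- build: pool tables, screen, enumerate ------------------------------
  kinds <- c(tf_gene = "TF_GENE", tf_mirna = "TF_MIRNA",
             mirna_gene = "MIRNA_GENE", mirna_tf = "MIRNA_TF")
  tables <- list()
  for (nm in names(kinds)) {
    if (!is.null(config[[nm]])) {
      tab <- suppressWarnings(read_edge_table(config[[nm]], kinds[[nm]]))
      rep <- attr(tab, "load_report")
      log_msg("%s: %d edges (%d rows, %d skipped)", kinds[[nm]],
              rep$rows_kept, rep$rows_in, rep$skipped)
      tables[[nm]] <- tab
    }
  }
  network <- assemble(tables, evidence_mode = config$evidence,
                      cancer = config$cancer)
  log_msg("assembled network: %d nodes, %d edges (evidence %s)",
          nrow(network$nodes), nrow(network$edges), config$evidence)

  screened <- network
  if (!is.null(config$cancer_genes) || !is.null(config$cancer_mirnas)) {
    cg <- if (is.null(config$cancer_genes)) character() else
      suppressWarnings(read_node_list(config$cancer_genes))
    cm <- if (is.null(config$cancer_mirnas)) character() else
      suppressWarnings(read_node_list(config$cancer_mirnas))
    screened <- screen_cancer(network, cg, cm)
    log_msg("cancer screening: %d nodes, %d edges retained",
            nrow(screened$nodes), nrow(screened$edges))
  }

  motifs <- enumerate_motifs(
    screened, allow_tf_targets = config$allow_tf_targets,
    pairs_include_ffl_triads = config$pairs_include_ffl_triads)
  if (config$mode == "SUBGRAPH") {
    qry <- read_node_list(config$query)
    motifs <- restrict_to_query(motifs, qry)
    log_msg("subgraph mode: %d motifs touch the query", nrow(motifs))
  }
  counts_before <- motif_class_counts(motifs)
  log_msg("motifs: %s",
          paste(names(counts_before), counts_before, sep = "=",
                collapse = " "))
  write_tsv(as.data.frame(motifs), file.path(config$out, "motifs.tsv"))

  ## -- refine -------------------------------------------------------------
  refined <- motifs
  counts_after <- counts_before
  did_refine <- FALSE
  if (want("refine") && !is.null(config$gene_expression) &&
      !is.null(config$mirna_expression)) {
    expr <- read_expression(config$gene_expression, config$mirna_expression)
    refined <- refine_motifs(motifs, expr, config$policy)
    counts_after <- motif_class_counts(refined)
    did_refine <- TRUE
    log_msg("refinement: %d of %d motifs retained", nrow(refined),
            nrow(motifs))
    write_tsv(as.data.frame(refined),
              file.path(config$out, "motifs_refined.tsv"))
  }

  coreg <- build_coreg_network(refined, screened)
  log_msg("co-regulatory network: %d nodes, %d edges", nrow(coreg$nodes),
          nrow(coreg$edges))
  write_network(coreg, file.path(config$out, "coreg_network.graphml"),
                "GRAPHML")
  write_network(coreg, file.path(config$out, "coreg_network.json"), "JSON")

  ## -- topology -----------------------------------------------------------
  topo <- NULL
  ranking <- NULL
  if (want("topology") && nrow(coreg$edges) > 0L) {
    topo <- suppressWarnings(topology_scores(coreg))
    write_tsv(topo, file.path(config$out, "topology_scores.tsv"))
    ranking <- do.call(rbind, lapply(c("DEGREE", "HUB", "AUTHORITY"),
                                     function(ind) {
      r <- rank_motifs(refined[, c("motif_class", "tf", "mirna", "target")],
                       topo, ind)
      if (nrow(r)) r$indicator <- ind else r$indicator <- character()
      r
    }))
    write_tsv(ranking, file.path(config$out, "motif_ranking.tsv"))
  }

  ## -- enrichment ---------------------------------------------------------
  enr <- list(genes = NULL, mirnas = NULL)
  if (want("enrich") && nrow(coreg$edges) > 0L) {
    gsets <- if (!is.null(config$gene_sets)) read_gmt(config$gene_sets)
    msets <- if (!is.null(config$mirna_sets)) read_gmt(config$mirna_sets)
    if (!is.null(gsets) || !is.null(msets)) {
      enr <- enrich_network(coreg, gene_sets = gsets, mirna_sets = msets,
                            background_network = network)
      if (!is.null(enr$genes)) {
        write_tsv(enr$genes, file.path(config$out, "enrichment_genes.tsv"))
      }
      if (!is.null(enr$mirnas)) {
        write_tsv(enr$mirnas, file.path(config$out, "enrichment_mirnas.tsv"))
      }
    }
  }

  summary <- list(
    cancer = config$cancer, evidence = config$evidence, mode = config$mode,
    seed = config$seed,
    network = list(nodes = nrow(network$nodes), edges = nrow(network$edges)),
    screened = list(nodes = nrow(screened$nodes),
                    edges = nrow(screened$edges)),
    coreg_network = list(nodes = nrow(coreg$nodes),
                         edges = nrow(coreg$edges)),
    motifs_before_refinement = as.list(counts_before),
    motifs_after_refinement = as.list(counts_after),
    refined = did_refine)
  jsonlite::write_json(summary, file.path(config$out, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(network = network, screened = screened, motifs = motifs,
                 refined = refined, coreg = coreg, topology = topo,
                 ranking = ranking, enrichment = enr, summary = summary))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a synthetic study to disk
#'
#' Materialises the outputs of [generate_regulatory_db()] and
#' [generate_expression()] as the external file formats the pipeline reads
#' (four edge-table TSVs, two cancer node lists, two expression TSVs, a
#' ground-truth motif table), so that a full run can be driven from files.
#'
#' @param config a [synthesis_config()].
#' @param dir output directory.
#' @return invisibly, a named list of the written paths plus the in-memory
#'   `db` and `expr` objects.
#' @export
write_synthetic_study <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  db <- generate_regulatory_db(config)
  expr <- generate_expression(db, config)
  paths <- list(
    tf_gene = file.path(dir, "tf_gene.tsv"),
    tf_mirna = file.path(dir, "tf_mirna.tsv"),
    mirna_gene = file.path(dir, "mirna_gene.tsv"),
    mirna_tf = file.path(dir, "mirna_tf.tsv"),
    cancer_genes = file.path(dir, "cancer_genes.txt"),
    cancer_mirnas = file.path(dir, "cancer_mirnas.txt"),
    gene_expression = file.path(dir, "gene_expression.tsv"),
    mirna_expression = file.path(dir, "mirna_expression.tsv"),
    truth = file.path(dir, "truth_motifs.tsv"))
  kinds <- c(tf_gene = "TF_GENE", tf_mirna = "TF_MIRNA",
             mirna_gene = "MIRNA_GENE", mirna_tf = "MIRNA_TF")
  for (nm in names(kinds)) {
    tab <- db$tables[[kinds[[nm]]]]
    utils::write.table(
      data.frame(tab$source, tab$target, tolower(tab$evidence)),
      paths[[nm]], sep = "\t", quote = FALSE, row.names = FALSE,
      col.names = FALSE)
  }
  write_node_list(db$cancer_genes, paths$cancer_genes)
  write_node_list(db$cancer_mirnas, paths$cancer_mirnas)
  write_expr_matrix(expr$gene, paths$gene_expression)
  write_expr_matrix(expr$mirna, paths$mirna_expression)
  write_tsv(db$truth$motifs, paths$truth)
  invisible(c(paths, list(db = db, expr = expr)))
}
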