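# Synthetic regulatory databases and expression bundles with planted motifs
# and planted correlation structure. The generator makes every pipeline stage
# testable without external databases: planted motifs are node-disjoint (so
# ground truth is stable under background-edge sampling), decoy motifs are
# structurally identical but expression-null, and everything is reproducible
# from the seed.

#' Configuration for the synthetic generator
#'
#' @param n_tf,n_mirna,n_gene node counts per class; must be at least the
#'   total number of planted + decoy motifs (each motif consumes one node of
#'   each class so that planted classes cannot be altered by background
#'   edges).
#' @param densities named numeric vector of background edge densities in
#'   \[0, 1\] per interaction kind (over pairs of non-motif nodes).
#' @param planted named integer vector of motif counts per class
#'   (`COREG_PAIR`, `TF_FFL`, `MIRNA_FFL`, `COMPOSITE_FFL`).
#' @param decoy_fraction fraction (of the planted total) of additional decoy
#'   motifs: structurally present, expression-null.
#' @param n_samples expression sample count.
#' @param effect_rho target Spearman magnitude in (0, 1) for planted
#'   regulator-target correlations.
#' @param seed integer RNG seed.
#' @return a list of class `"synthesis_config"`.
#' @export
synthesis_config <- function(n_tf = 30, n_mirna = 30, n_gene = 60,
                             densities = c(TF_GENE = 0.02, TF_MIRNA = 0.02,
                                           MIRNA_GENE = 0.02, MIRNA_TF = 0.02),
                             planted = c(COREG_PAIR = 5, TF_FFL = 3,
                                         MIRNA_FFL = 2, COMPOSITE_FFL = 2),
                             decoy_fraction = 0.5,
                             n_samples = 100, effect_rho = 0.6, seed = 1L) {
  planted <- planted[MOTIF_CLASSES]
  planted[is.na(planted)] <- 0L
  names(planted) <- MOTIF_CLASSES
  densities <- densities[INTERACTION_KINDS]
  densities[is.na(densities)] <- 0
  names(densities) <- INTERACTION_KINDS
  stopifnot(n_tf >= 1, n_mirna >= 1, n_gene >= 1,
            all(densities >= 0 & densities <= 1),
            all(planted >= 0), decoy_fraction >= 0, decoy_fraction <= 1,
            n_samples >= 3, effect_rho > 0, effect_rho < 1)
  structure(list(n_tf = as.integer(n_tf), n_mirna = as.integer(n_mirna),
                 n_gene = as.integer(n_gene), densities = densities,
                 planted = as.integer(stats::setNames(planted, MOTIF_CLASSES)),
                 decoy_fraction = decoy_fraction,
                 n_samples = as.integer(n_samples),
                 effect_rho = effect_rho, seed = as.integer(seed)),
            class = "synthesis_config")
}

## Edges realising one motif of a class, with construction signs
## (+1 / -1 intended correlation for each planted edge).
motif_edge_plan <- function(motif_class, tf, mirna, gene) {
  e <- function(source, target, kind, sign) {
    data.frame(source = source, target = target, interaction_kind = kind,
               sign = sign, stringsAsFactors = FALSE)
  }
  switch(motif_class,
    COREG_PAIR = rbind(e(tf, gene, "TF_GENE", +1),
                       e(mirna, gene, "MIRNA_GENE", -1)),
    TF_FFL = rbind(e(tf, gene, "TF_GENE", -1),
                   e(mirna, gene, "MIRNA_GENE", -1),
                   e(tf, mirna, "TF_MIRNA", +1)),
    MIRNA_FFL = rbind(e(tf, gene, "TF_GENE", +1),
                      e(mirna, gene, "MIRNA_GENE", -1),
                      e(mirna, tf, "MIRNA_TF", -1)),
    COMPOSITE_FFL = rbind(e(tf, gene, "TF_GENE", +1),
                          e(mirna, gene, "MIRNA_GENE", -1),
                          e(tf, mirna, "TF_MIRNA", -1),
                          e(mirna, tf, "MIRNA_TF", -1)))
}

#' Generate a synthetic regulatory database with planted motifs
#'
#' Plants the configured motif counts on node-disjoint (TF, miRNA, gene)
#' triples, adds `decoy_fraction` of the planted total as decoy motifs (same
#' structural classes, cycled), samples background edges among the remaining
#' nodes at the configured densities, and assigns evidence labels (planted
#' and decoy edges carry both levels so they survive any evidence mode;
#' background edges a validated/predicted mixture). Cancer lists contain all
#' motif members plus a random 30% of background nodes. Fully reproducible
#' from the seed.
#'
#' @param config a [synthesis_config()].
#' @return list with `tables` (named list of four [edge_table()]s),
#'   `cancer_genes`, `cancer_mirnas`, `nodes` (list of all ids per class),
#'   and `truth` (list: `motifs` data frame with `is_decoy`; `edges` data
#'   frame with planted signs).
#' @export
generate_regulatory_db <- function(config) {
  stopifnot(inherits(config, "synthesis_config"))
  set.seed(config$seed)

  n_signal <- sum(config$planted)
  n_decoy <- round(config$decoy_fraction * n_signal)
  m_total <- n_signal + n_decoy
  if (m_total > min(config$n_tf, config$n_mirna, config$n_gene)) {
    stop("unrealizable planting: ", m_total, " motifs need at least that ",
         "many nodes of each class")
  }

  tfs <- sprintf("TF%03d", seq_len(config$n_tf))
  mirs <- sprintf("hsa-mir-%03d", seq_len(config$n_mirna))
  genes <- sprintf("G%04d", seq_len(config$n_gene))

  classes <- rep(MOTIF_CLASSES, times = config$planted)
  decoy_classes <- if (n_decoy > 0) {
    rep(MOTIF_CLASSES[config$planted > 0],
        length.out = n_decoy)
  } else character()
  all_classes <- c(classes, decoy_classes)
  is_decoy <- c(rep(FALSE, n_signal), rep(TRUE, n_decoy))

  motifs <- data.frame(motif_class = all_classes,
                       tf = tfs[seq_len(m_total)],
                       mirna = mirs[seq_len(m_total)],
                       target = genes[seq_len(m_total)],
                       is_decoy = is_decoy, stringsAsFactors = FALSE)

  planted_edges <- do.call(rbind, lapply(seq_len(nrow(motifs)), function(i) {
    p <- motif_edge_plan(motifs$motif_class[i], motifs$tf[i],
                         motifs$mirna[i], motifs$target[i])
    p$is_decoy <- motifs$is_decoy[i]
    p
  }))
  if (is.null(planted_edges)) {
    planted_edges <- data.frame(source = character(), target = character(),
                                interaction_kind = character(),
                                sign = numeric(), is_decoy = logical(),
                                stringsAsFactors = FALSE)
  }

  ## background edges among non-motif nodes only
  bg_tf <- tfs[-seq_len(m_total)]
  bg_mir <- mirs[-seq_len(m_total)]
  bg_gene <- genes[-seq_len(m_total)]
  sample_pairs <- function(src, tgt, density) {
    if (density == 0 || !length(src) || !length(tgt)) {
      return(data.frame(source = character(), target = character(),
                        stringsAsFactors = FALSE))
    }
    grid <- expand.grid(source = src, target = tgt, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    grid[stats::runif(nrow(grid)) < density, , drop = FALSE]
  }
  bg <- list(
    TF_GENE = sample_pairs(bg_tf, bg_gene, config$densities[["TF_GENE"]]),
    TF_MIRNA = sample_pairs(bg_tf, bg_mir, config$densities[["TF_MIRNA"]]),
    MIRNA_GENE = sample_pairs(bg_mir, bg_gene,
                              config$densities[["MIRNA_GENE"]]),
    MIRNA_TF = sample_pairs(bg_mir, bg_tf, config$densities[["MIRNA_TF"]]))

  ev_levels <- c("VALIDATED", "PREDICTED", "PREDICTED,VALIDATED")
  tables <- lapply(INTERACTION_KINDS, function(kind) {
    pl <- planted_edges[planted_edges$interaction_kind == kind, , drop = FALSE]
    b <- bg[[kind]]
    src <- c(pl$source, b$source)
    tgt <- c(pl$target, b$target)
    ev <- c(rep("PREDICTED,VALIDATED", nrow(pl)),
            sample(ev_levels, nrow(b), replace = TRUE,
                   prob = c(0.5, 0.4, 0.1)))
    edge_table(src, tgt, interaction_kind = kind, evidence = ev,
               provenance = "synthetic")
  })
  names(tables) <- INTERACTION_KINDS

  cancer_genes <- unique(c(motifs$tf, motifs$target,
                           sample(bg_gene, max(0, round(0.3 * length(bg_gene)))),
                           sample(bg_tf, max(0, round(0.3 * length(bg_tf))))))
  cancer_mirnas <- unique(c(motifs$mirna,
                            sample(bg_mir,
                                   max(0, round(0.3 * length(bg_mir))))))

  list(tables = tables,
       cancer_genes = cancer_genes,
       cancer_mirnas = cancer_mirnas,
       nodes = list(tf = tfs, mirna = mirs, gene = genes),
       truth = list(motifs = motifs, edges = planted_edges))
}

#' Generate an expression bundle matching a synthetic ground truth
#'
#' Regulator features are i.i.d. standard normal across samples. Within each
#' planted (non-decoy) motif the members are multivariate normal with the
#' planted pairwise correlation signs, scaled so each planted edge's expected
#' Spearman magnitude is about `effect_rho` (direct regulator-target edges;
#' the TF-target edge of an FFL whose effect is routed through the partner
#' regulator attains magnitude about `effect_rho^2`). Decoy-motif members and
#' all background nodes get independent noise.
#'
#' @param db output of [generate_regulatory_db()].
#' @param config the same [synthesis_config()].
#' @return an `"expression_bundle"` with genes and TFs in the gene matrix and
#'   miRNAs in the miRNA matrix.
#' @export
generate_expression <- function(db, config) {
  stopifnot(inherits(config, "synthesis_config"))
  set.seed(config$seed + 1L)
  ns <- config$n_samples
  samples <- sprintf("S%04d", seq_len(ns))
  ## Pearson magnitude giving the target Spearman magnitude under normality
  rp <- 2 * sin(pi * config$effect_rho / 6)

  gene_ids <- c(db$nodes$tf, db$nodes$gene)
  gmat <- matrix(stats::rnorm(length(gene_ids) * ns), ncol = ns,
                 dimnames = list(gene_ids, samples))
  mmat <- matrix(stats::rnorm(length(db$nodes$mirna) * ns), ncol = ns,
                 dimnames = list(db$nodes$mirna, samples))

  noise <- function() stats::rnorm(ns)
  mix <- function(driver, r) r * driver + sqrt(1 - r^2) * noise()

  motifs <- db$truth$motifs
  for (i in seq_len(nrow(motifs))) {
    if (motifs$is_decoy[i]) next  # decoys keep their independent noise
    tf <- motifs$tf[i]; mir <- motifs$mirna[i]; g <- motifs$target[i]
    switch(motifs$motif_class[i],
      COREG_PAIR = {
        a <- min(rp, 0.7)  # equal-magnitude loadings need a <= 1/sqrt(2)
        gmat[g, ] <- a * gmat[tf, ] - a * mmat[mir, ] +
          sqrt(max(1 - 2 * a^2, 1e-6)) * noise()
      },
      TF_FFL = {
        mmat[mir, ] <- mix(gmat[tf, ], rp)
        gmat[g, ] <- mix(mmat[mir, ], -rp)
      },
      MIRNA_FFL = {
        gmat[tf, ] <- mix(mmat[mir, ], -rp)
        gmat[g, ] <- mix(mmat[mir, ], -rp)
      },
      COMPOSITE_FFL = {
        mmat[mir, ] <- mix(gmat[tf, ], -rp)
        gmat[g, ] <- mix(mmat[mir, ], -rp)
      })
  }
  expression_bundle(gmat, mmat)
}
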