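# Shared fixtures: the three-edge ovarian-cancer worked example, random typed
# networks, and independent brute-force oracles used against the package's
# own implementations.

## A well-documented ovarian-cancer TF-FFL: TP53 regulates hsa-mir-29c and PTEN,
## the miRNA represses PTEN.
ov_network <- function() {
  assemble(list(
    edge_table("TP53", "PTEN", "TF_GENE"),
    edge_table("TP53", "hsa-mir-29c", "TF_MIRNA"),
    edge_table("hsa-mir-29c", "PTEN", "MIRNA_GENE")),
    evidence_mode = "VALIDATED", cancer = "OV")
}

## Random typed network built directly from Bernoulli edge tables.
random_typed_network <- function(seed, n_tf = 6, n_mir = 6, n_gene = 12,
                                 p = 0.15) {
  set.seed(seed)
  tfs <- sprintf("T%02d", seq_len(n_tf))
  mirs <- sprintf("hsa-mir-%02d", seq_len(n_mir))
  genes <- sprintf("g%03d", seq_len(n_gene))
  rnd_table <- function(src, tgt, kind) {
    grid <- expand.grid(s = src, t = tgt, stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) < p, , drop = FALSE]
    edge_table(grid$s, grid$t, interaction_kind = kind,
               evidence = sample(c("VALIDATED", "PREDICTED"), nrow(grid),
                                 replace = TRUE))
  }
  assemble(list(rnd_table(tfs, genes, "TF_GENE"),
                rnd_table(tfs, mirs, "TF_MIRNA"),
                rnd_table(mirs, genes, "MIRNA_GENE"),
                rnd_table(mirs, tfs, "MIRNA_TF")), "BOTH")
}

## Independent brute-force motif oracle: triple loop over all
## TF x miRNA x gene-target combinations, checking raw edge presence.
oracle_motifs <- function(network) {
  ed <- network$edges
  has <- function(a, b) any(ed$source == a & ed$target == b)
  nodes <- network$nodes
  tfs <- nodes$id[nodes$node_class == "TF"]
  mirs <- nodes$id[nodes$node_class == "MIRNA"]
  genes <- nodes$id[nodes$node_class == "GENE"]
  rows <- list()
  for (tf in tfs) for (mi in mirs) for (g in genes) {
    if (!has(tf, g) || !has(mi, g)) next
    t2m <- has(tf, mi)
    m2t <- has(mi, tf)
    cls <- if (t2m && m2t) "COMPOSITE_FFL" else if (t2m) "TF_FFL"
           else if (m2t) "MIRNA_FFL" else "COREG_PAIR"
    rows[[length(rows) + 1L]] <- data.frame(
      motif_class = cls, tf = tf, mirna = mi, target = g,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(motif_class = character(), tf = character(),
               mirna = character(), target = character(),
               stringsAsFactors = FALSE)
  out <- out[order(out$tf, out$mirna, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## All permutations of 1..n (for the exhaustive Spearman permutation oracle).
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

## Exhaustive two-sided permutation p-value for Spearman's rho.
perm_spearman_p <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  perms <- all_perms(n)
  rhos <- apply(perms, 1, function(idx) cor(rx, ry[idx]))
  mean(abs(rhos) >= obs - 1e-12)
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
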