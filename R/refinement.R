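# Expression-based refinement of co-regulatory motifs. Each motif member
# edge is tested against pairwise Spearman correlation computed from matched
# gene and miRNA expression matrices, with p-value, magnitude, and sign rules:
#   miRNA-source edges pass iff p < alpha and rho <= -c (miRNAs repress);
#   TF-source edges   pass iff p < alpha and |rho| >= c (or one sign only,
#                     when positive-only or negative-only TF regulation is
#                     requested).
# A motif is retained iff every member edge passes.

#' Filtering policy for expression refinement
#'
#' @param alpha p-value cutoff in (0, 1]; edges pass at p strictly below it.
#' @param coeff_cutoff non-negative correlation-magnitude cutoff `c` in
#'   \[0, 1\]; compared non-strictly (|rho| >= c, rho <= -c).
#' @param tf_sign which TF-target correlations count: `"BOTH"` (|rho| >= c),
#'   `"POSITIVE"` (rho >= c), or `"NEGATIVE"` (rho <= -c).
#' @param drop_unmeasured whether edges with no defined correlation record
#'   (a member absent from the expression data, or fewer than 3 complete
#'   sample pairs) fail (`TRUE`, default) or pass unfiltered (`FALSE`).
#' @return a list of class `"filter_policy"`.
#' @export
filter_policy <- function(alpha = 0.05, coeff_cutoff = 0.2,
                          tf_sign = c("BOTH", "POSITIVE", "NEGATIVE"),
                          drop_unmeasured = TRUE) {
  tf_sign <- match.arg(toupper(tf_sign[1]), c("BOTH", "POSITIVE", "NEGATIVE"))
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha <= 1,
            is.numeric(coeff_cutoff), length(coeff_cutoff) == 1L,
            coeff_cutoff >= 0, coeff_cutoff <= 1)
  structure(list(alpha = alpha, coeff_cutoff = coeff_cutoff,
                 tf_sign = tf_sign, drop_unmeasured = isTRUE(drop_unmeasured)),
            class = "filter_policy")
}

#' Spearman correlation record with a t-approximation p-value
#'
#' Computes Spearman's rho as the Pearson correlation of average (mid-) ranks
#' over pairwise-complete observations, with a two-sided p-value from the
#' t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on `n - 2` degrees
#' of freedom. `|rho| = 1` gives `p = 0`. Fewer than 3 complete pairs, or a
#' tie-degenerate (constant-rank) vector, yields an unmeasured record
#' (`rho = NA`, `p = NA`).
#'
#' @param x,y numeric vectors of equal length; `NA`s are removed pairwise.
#' @return a one-row data frame: `rho`, `p`, `n` (complete pairs),
#'   `measured` (logical).
#' @export
spearman_record <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  n <- sum(ok)
  if (n < 3L) {
    return(data.frame(rho = NA_real_, p = NA_real_, n = n, measured = FALSE))
  }
  rx <- rank(x[ok])
  ry <- rank(y[ok])
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(data.frame(rho = NA_real_, p = NA_real_, n = n, measured = FALSE))
  }
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
    rho <- sign(rho)
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  }
  data.frame(rho = rho, p = p, n = n, measured = TRUE)
}

#' Does one edge pass the refinement policy?
#'
#' @param mirna_source logical: is the regulator a miRNA (kinds MIRNA_GENE and
#'   MIRNA_TF)? Otherwise the TF-target rule applies (kinds TF_GENE and
#'   TF_MIRNA).
#' @param record a record from [spearman_record()] (or `NULL` for unmeasured).
#' @param policy a [filter_policy()].
#' @return logical.
#' @export
edge_passes <- function(mirna_source, record, policy) {
  if (is.null(record) || !isTRUE(record$measured)) {
    return(!policy$drop_unmeasured)
  }
  rho <- record$rho
  p <- record$p
  cc <- policy$coeff_cutoff
  if (p >= policy$alpha) return(FALSE)
  if (mirna_source) return(rho <= -cc)
  switch(policy$tf_sign,
         BOTH = abs(rho) >= cc,
         POSITIVE = rho >= cc,
         NEGATIVE = rho <= -cc)
}

## Look up an expression row for a node id. TF and gene ids resolve against
## the gene matrix (case-sensitive); miRNA ids against the miRNA matrix
## (case-insensitive).
expr_row <- function(expr, id, mirna) {
  if (mirna) {
    hit <- match(tolower(id), tolower(rownames(expr$mirna)))
    if (is.na(hit)) NULL else expr$mirna[hit, ]
  } else {
    if (!id %in% rownames(expr$gene)) NULL else expr$gene[id, ]
  }
}

#' Refine motifs against expression data
#'
#' Computes a Spearman correlation record for every distinct member edge of
#' the motif collection and retains a motif iff all of its member edges pass
#' the policy (see [edge_passes()]). Regulator-side class decides the rule:
#' miRNA-source edges need negative correlation; TF-source edges follow the
#' `tf_sign` mode.
#'
#' @param motifs a `"motif_table"` from [enumerate_motifs()].
#' @param expr an `"expression_bundle"`.
#' @param policy a [filter_policy()].
#' @return the retained `"motif_table"` with per-edge record columns appended
#'   (`rho_<role>`, `p_<role>` for roles `tf_target`, `mirna_target`,
#'   `tf_mirna`, `mirna_tf`; `NA` where a motif lacks the role). The full
#'   per-edge record table is attached as attribute `"edge_records"`.
#' @export
refine_motifs <- function(motifs, expr, policy = filter_policy()) {
  mem <- motif_member_edges(motifs)
  if (nrow(motifs) == 0L) return(motifs)

  ## regulator class per edge role: sources of tf_* roles are TFs, of
  ## mirna_* roles miRNAs; targets of tf_mirna are miRNAs
  src_is_mir <- mem$mirna_source
  tgt_is_mir <- mem$role == "tf_mirna"

  pair_key <- paste(node_key(mem$source, ifelse(src_is_mir, "MIRNA", "TF")),
                    node_key(mem$target, ifelse(tgt_is_mir, "MIRNA", "GENE")),
                    sep = "\r")
  uniq <- !duplicated(pair_key)
  recs <- vector("list", sum(uniq))
  names(recs) <- pair_key[uniq]
  for (i in which(uniq)) {
    xs <- expr_row(expr, mem$source[i], src_is_mir[i])
    ys <- expr_row(expr, mem$target[i], tgt_is_mir[i])
    recs[[pair_key[i]]] <- if (is.null(xs) || is.null(ys)) {
      data.frame(rho = NA_real_, p = NA_real_, n = 0L, measured = FALSE)
    } else {
      spearman_record(xs, ys)
    }
  }
  rec_tab <- do.call(rbind, recs[pair_key])
  mem$rho <- rec_tab$rho
  mem$p <- rec_tab$p
  mem$n <- rec_tab$n
  mem$measured <- rec_tab$measured
  mem$pass <- vapply(seq_len(nrow(mem)), function(i) {
    edge_passes(mem$mirna_source[i], mem[i, c("rho", "p", "measured")], policy)
  }, logical(1))

  if (!any(mem$measured)) {
    warning("no motif member edge could be measured in the expression data")
  }

  keep_idx <- tapply(mem$pass, mem$motif_idx, all)
  keep <- which(as.logical(keep_idx[as.character(seq_len(nrow(motifs)))]))
  out <- motifs[keep, , drop = FALSE]

  ## append per-role rho/p columns for reporting
  for (role in c("tf_target", "mirna_target", "tf_mirna", "mirna_tf")) {
    sub <- mem[mem$role == role & mem$motif_idx %in% keep, , drop = FALSE]
    rho_col <- rep(NA_real_, nrow(out))
    p_col <- rep(NA_real_, nrow(out))
    pos <- match(sub$motif_idx, keep)
    rho_col[pos] <- sub$rho
    p_col[pos] <- sub$p
    out[[paste0("rho_", role)]] <- rho_col
    out[[paste0("p_", role)]] <- p_col
  }
  rownames(out) <- NULL
  attr(out, "edge_records") <- mem
  class(out) <- c("motif_table", "data.frame")
  out
}
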