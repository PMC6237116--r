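# Node-level topology indicators for the co-regulatory network: degree and
# the HITS hub/authority scores. With A the directed adjacency matrix over a
# fixed node ordering, the hub score is the principal eigenvector of A A^T
# and the authority score the principal eigenvector of A^T A; both are
# computed by power iteration and rescaled so the maximum entry is 1.

#' Degree, hub, and authority scores for every node
#'
#' @param network a `"typed_network"` with at least one edge.
#' @param tol power-iteration convergence tolerance (max absolute change of
#'   the unit-normalised iterate between sweeps).
#' @param max_iter iteration cap; exceeding it without convergence is an
#'   error reporting the residual.
#' @return data frame with columns `id`, `node_class`, `degree`
#'   (in-degree + out-degree), `hub`, `authority`, sorted by id. Hub and
#'   authority are non-negative with maximum 1.
#' @export
topology_scores <- function(network, tol = 1e-10, max_iter = 10000L) {
  nodes <- network$nodes
  if (nrow(network$edges) == 0L) stop("network has no edges")
  ids <- sort(nodes$id)
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  A[cbind(match(network$edges$source, ids),
          match(network$edges$target, ids))] <- 1

  hub <- power_iterate(function(v) A %*% (crossprod(A, v)), n, tol, max_iter)
  authority <- power_iterate(function(v) crossprod(A, A %*% v), n, tol,
                             max_iter)

  ## flag (near-)degenerate principal eigenvalue of AA^T: the principal
  ## eigenvector is then not unique and scores depend on the start vector
  ev <- eigen(tcrossprod(A), symmetric = TRUE, only.values = TRUE)$values
  if (n >= 2 && (ev[1] - ev[2]) < 1e-8) {
    warning("principal eigenvalue of AA^T is (near-)degenerate; ",
            "hub/authority scores may not be unique")
  }

  deg <- as.integer(rowSums(A) + colSums(A))
  data.frame(id = ids,
             node_class = nodes$node_class[match(ids, nodes$id)],
             degree = deg,
             hub = hub / max(hub),
             authority = authority / max(authority),
             stringsAsFactors = FALSE)
}

## Power iteration for a symmetric PSD operator given as multiply(v).
## Uniform positive start; L2 normalisation each sweep; returns the
## non-negative eigenvector (not yet max-rescaled).
power_iterate <- function(multiply, n, tol, max_iter) {
  v <- rep(1 / sqrt(n), n)
  for (iter in seq_len(max_iter)) {
    w <- as.numeric(multiply(v))
    nrm <- sqrt(sum(w^2))
    if (nrm == 0) return(rep(0, n))  # operator annihilates the start vector
    w <- w / nrm
    if (max(abs(w - v)) < tol) return(abs(w))
    v <- w
  }
  stop(sprintf("power iteration did not converge in %d iterations (residual %g)",
               max_iter, max(abs(w - v))))
}

#' Topology score of a motif
#'
#' The sum of one indicator over the motif's three member nodes, used to rank
#' motifs within each class.
#'
#' @param motifs a `"motif_table"`.
#' @param scores a score table from [topology_scores()].
#' @param indicator `"DEGREE"`, `"HUB"`, or `"AUTHORITY"`.
#' @return numeric vector of scores, one per motif; `NA` (with a warning) for
#'   motifs with an unscored member.
#' @export
motif_score <- function(motifs, scores, indicator = c("DEGREE", "HUB",
                                                      "AUTHORITY")) {
  indicator <- match.arg(toupper(indicator[1]), c("DEGREE", "HUB", "AUTHORITY"))
  col <- c(DEGREE = "degree", HUB = "hub", AUTHORITY = "authority")[[indicator]]
  val <- stats::setNames(scores[[col]], scores$id)
  out <- val[motifs$tf] + val[motifs$mirna] + val[motifs$target]
  out <- unname(out)
  if (anyNA(out) && nrow(motifs)) {
    warning(sum(is.na(out)), " motif(s) with unscored members excluded ",
            "from ranking")
  }
  out
}

#' Rank motifs within each class by a topology indicator
#'
#' @inheritParams motif_score
#' @return the motif table with a `score` column, sorted by class then
#'   descending score; motifs with unscored members are dropped.
#' @export
rank_motifs <- function(motifs, scores, indicator = "DEGREE") {
  s <- suppressWarnings(motif_score(motifs, scores, indicator))
  out <- motifs
  out$score <- s
  out <- out[!is.na(s), , drop = FALSE]
  out <- out[order(out$motif_class, -out$score, out$tf, out$mirna,
                   out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
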