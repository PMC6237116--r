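# Spearman records, edge pass rules, and motif refinement.

test_that("spearman rho is exact on monotone closed forms", {
  expect_equal(spearman_record(1:5, c(2, 4, 6, 8, 10))$rho, 1)
  expect_equal(spearman_record(1:5, c(10, 8, 6, 4, 2))$rho, -1)
  expect_equal(spearman_record(1:5, c(2, 4, 6, 8, 10))$p, 0)
  # invariant under strictly increasing transforms
  set.seed(10)
  x <- rnorm(25); y <- rnorm(25)
  expect_equal(spearman_record(exp(x), y)$rho, spearman_record(x, y)$rho)
  expect_equal(spearman_record(x, y^3 + 5 * y)$rho,
               spearman_record(x, y)$rho)
  # symmetry
  expect_equal(spearman_record(x, y)$rho, spearman_record(y, x)$rho)
  # midranks agree with the standard implementation under ties
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 6, 6)
  expect_equal(spearman_record(xt, yt)$rho,
               cor(xt, yt, method = "spearman"))
})

test_that("pairwise deletion and the unmeasured threshold", {
  x <- c(1, 2, NA, 4, 5)
  y <- c(2, NA, 3, 8, 10)
  rec <- spearman_record(x, y)
  expect_equal(rec$n, 3L)
  expect_equal(rec$rho, 1)
  expect_false(spearman_record(c(1, 2, NA, NA), c(1, 2, 3, 4))$measured)
  expect_false(spearman_record(c(1, 1, 1, 1), 1:4)$measured)  # constant ranks
})

test_that("t-approximation p tracks the exhaustive permutation p", {
  set.seed(77)
  worst <- 0
  for (n in c(6, 7, 8)) {
    for (rep in 1:8) {
      x <- rnorm(n); y <- rnorm(n)
      rec <- spearman_record(x, y)
      p_perm <- perm_spearman_p(x, y)
      worst <- max(worst, abs(rec$p - p_perm))
    }
  }
  expect_lt(worst, 0.05)

  # at n = 5 the permutation null is so coarse (two-sided steps of ~1/60)
  # that the worst-case gap to any smooth approximation widens; it stays
  # below 0.08
  for (rep in 1:8) {
    x <- rnorm(5); y <- rnorm(5)
    expect_lt(abs(spearman_record(x, y)$p - perm_spearman_p(x, y)), 0.08)
  }
})

test_that("edge pass rules implement the sign and threshold conventions", {
  pol <- filter_policy(alpha = 0.05, coeff_cutoff = 0.2, tf_sign = "BOTH")
  rec <- function(rho, p) data.frame(rho = rho, p = p, n = 50, measured = TRUE)
  # miRNA edges: p < alpha and rho <= -c
  expect_true(edge_passes(TRUE, rec(-0.35, 0.001), pol))
  expect_false(edge_passes(TRUE, rec(0.35, 0.001), pol))
  expect_true(edge_passes(TRUE, rec(-0.2, 0.01), pol))   # non-strict at -c
  expect_false(edge_passes(TRUE, rec(-0.19, 0.01), pol))
  expect_false(edge_passes(TRUE, rec(-0.5, 0.05), pol))  # strict at alpha
  # TF edges by sign mode
  expect_true(edge_passes(FALSE, rec(-0.25, 0.01), pol))
  expect_true(edge_passes(FALSE, rec(0.25, 0.01), pol))
  pos <- filter_policy(tf_sign = "POSITIVE")
  expect_false(edge_passes(FALSE, rec(-0.25, 0.01), pos))
  expect_true(edge_passes(FALSE, rec(0.25, 0.01), pos))
  neg <- filter_policy(tf_sign = "NEGATIVE")
  expect_true(edge_passes(FALSE, rec(-0.25, 0.01), neg))
  expect_false(edge_passes(FALSE, rec(0.25, 0.01), neg))
  # unmeasured records fall to drop_unmeasured
  un <- data.frame(rho = NA, p = NA, n = 0, measured = FALSE)
  expect_false(edge_passes(TRUE, un, pol))
  keep <- filter_policy(drop_unmeasured = FALSE)
  expect_true(edge_passes(TRUE, un, keep))
})

## deterministic bundle where the OV motif's edges have strong correct signs
ov_expression <- function(flip_mirna = FALSE) {
  set.seed(99)
  n <- 60
  tp53 <- rnorm(n)
  mir <- 0.9 * tp53 + 0.3 * rnorm(n)
  pten <- (if (flip_mirna) 0.9 else -0.9) * mir + 0.3 * rnorm(n)
  samples <- sprintf("s%02d", 1:n)
  expression_bundle(
    gene = rbind(TP53 = tp53, PTEN = pten)[, , drop = FALSE] |>
      (\(m) {colnames(m) <- samples; m})(),
    mirna = matrix(mir, 1, n, dimnames = list("hsa-mir-29c", samples)))
}

test_that("refinement retains motifs whose member edges all pass", {
  net <- ov_network()
  m <- enumerate_motifs(net)
  kept <- refine_motifs(m, ov_expression(), filter_policy())
  expect_equal(nrow(kept), 1L)
  expect_lt(kept$rho_mirna_target, -0.2)
  expect_gt(kept$rho_tf_mirna, 0.2)
  expect_false(is.na(kept$p_tf_target))
  # one wrong-sign miRNA edge drops the motif
  expect_equal(nrow(refine_motifs(m, ov_expression(flip_mirna = TRUE),
                                  filter_policy())), 0L)
})

test_that("motifs with unmeasured members follow drop_unmeasured", {
  net <- ov_network()
  m <- enumerate_motifs(net)
  expr <- ov_expression()
  expr$gene <- expr$gene["TP53", , drop = FALSE]  # PTEN unmeasured
  expect_equal(nrow(refine_motifs(m, expr, filter_policy())), 0L)
  expect_equal(nrow(refine_motifs(m, expr,
                                  filter_policy(drop_unmeasured = FALSE))), 1L)
})

test_that("tightening the policy never enlarges the retained set", {
  cfg <- synthesis_config(seed = 13)
  db <- generate_regulatory_db(cfg)
  expr <- generate_expression(db, cfg)
  net <- assemble(db$tables, "BOTH")
  m <- enumerate_motifs(net)
  key <- function(mm) paste(mm$tf, mm$mirna, mm$target)
  prev <- NULL
  for (cc in c(0, 0.2, 0.4)) {
    kept <- key(refine_motifs(m, expr, filter_policy(coeff_cutoff = cc)))
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
  prev <- NULL
  for (a in c(0.1, 0.01, 0.001)) {
    kept <- key(refine_motifs(m, expr, filter_policy(alpha = a)))
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
  # output is always a subset of the input
  all_keys <- key(m)
  expect_true(all(key(refine_motifs(m, expr, filter_policy())) %in% all_keys))
})
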