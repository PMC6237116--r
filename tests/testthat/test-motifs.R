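# Motif classification and enumeration.

test_that("the TP53/hsa-mir-29c/PTEN ovarian-cancer triad classifies as a TF-FFL", {
  net <- ov_network()
  expect_equal(classify_triad("TP53", "hsa-mir-29c", "PTEN", net), "TF_FFL")
  m <- enumerate_motifs(net)
  expect_equal(nrow(m), 1L)
  expect_equal(m$motif_class, "TF_FFL")
  expect_equal(unname(motif_class_counts(m)[c("COREG_PAIR", "MIRNA_FFL",
                                              "COMPOSITE_FFL")]),
               c(0L, 0L, 0L))
})

test_that("the four regulator-edge configurations partition the taxonomy", {
  base <- list(edge_table("T1", "g1", "TF_GENE"),
               edge_table("hsa-mir-1", "g1", "MIRNA_GENE"))
  t2m <- edge_table("T1", "hsa-mir-1", "TF_MIRNA")
  m2t <- edge_table("hsa-mir-1", "T1", "MIRNA_TF")
  cases <- list(
    COREG_PAIR = base,
    TF_FFL = c(base, list(t2m)),
    MIRNA_FFL = c(base, list(m2t)),
    COMPOSITE_FFL = c(base, list(t2m, m2t)))
  for (expected in names(cases)) {
    net <- assemble(cases[[expected]], "BOTH")
    expect_equal(classify_triad("T1", "hsa-mir-1", "g1", net), expected)
    m <- enumerate_motifs(net)
    expect_equal(nrow(m), 1L)  # exactly one class per triad
    expect_equal(m$motif_class, expected)
  }
  # missing a joint-target edge: no motif at all
  net <- assemble(list(edge_table("T1", "g1", "TF_GENE"), t2m, m2t), "BOTH")
  expect_true(is.na(classify_triad("T1", "hsa-mir-1", "g1", net)))
  expect_equal(nrow(enumerate_motifs(net)), 0L)
})

test_that("classify_triad validates node classes and distinctness", {
  net <- ov_network()
  expect_error(classify_triad("PTEN", "hsa-mir-29c", "TP53", net), "not a TF")
  expect_error(classify_triad("TP53", "PTEN", "PTEN", net), "not a miRNA")
  expect_error(classify_triad("TP53", "hsa-mir-29c", "hsa-mir-29c", net),
               "not a target")
})

test_that("enumeration equals the brute-force triple-loop oracle", {
  # many small seeded networks plus a few at the 60-node scale
  specs <- c(lapply(1:190, function(s) list(seed = s)),
             lapply(191:200, function(s) list(seed = s, n_tf = 15, n_mir = 15,
                                              n_gene = 30, p = 0.08)))
  checked_classes <- integer(4)
  names(checked_classes) <- c("COREG_PAIR", "TF_FFL", "MIRNA_FFL",
                              "COMPOSITE_FFL")
  for (sp in specs) {
    net <- do.call(random_typed_network, sp)
    got <- as.data.frame(enumerate_motifs(net))
    want <- oracle_motifs(net)
    expect_identical(got, want)
    tab <- table(want$motif_class)
    checked_classes[names(tab)] <- checked_classes[names(tab)] + tab
  }
  # the sweep actually exercised every motif class
  expect_true(all(checked_classes > 0))
})

test_that("empty network and deterministic ordering", {
  expect_equal(nrow(enumerate_motifs(typed_network())), 0L)
  net <- random_typed_network(33, p = 0.25)
  m <- enumerate_motifs(net)
  o <- order(m$tf, m$mirna, m$target)
  expect_equal(o, seq_len(nrow(m)))
  expect_identical(enumerate_motifs(net), m)
})

test_that("motif enumeration is monotone in the edge set", {
  net <- random_typed_network(44, p = 0.2)
  m_full <- enumerate_motifs(net)
  key <- function(m) paste(m$tf, m$mirna, m$target)
  set.seed(45)
  for (i in sample(nrow(net$edges), 5)) {
    sub <- typed_network(net$edges[-i, , drop = FALSE])
    m_sub <- enumerate_motifs(sub)
    # removing an edge never adds a triad
    expect_true(all(key(m_sub) %in% key(m_full)))
  }
})

test_that("query restriction keeps motifs touching the query", {
  net <- ov_network()
  m <- enumerate_motifs(net)
  expect_equal(nrow(restrict_to_query(m, "PTEN")), 1L)
  expect_equal(nrow(restrict_to_query(m, "HSA-MIR-29C")), 1L)  # miRNA, any case
  expect_equal(nrow(restrict_to_query(m, "BRCA1")), 0L)
  expect_warning(r <- restrict_to_query(m, character()), "empty query")
  expect_equal(nrow(r), 0L)

  big <- enumerate_motifs(random_typed_network(55, p = 0.2))
  set.seed(56)
  qry <- sample(unique(c(big$tf, big$mirna, big$target)), 5)
  kept <- restrict_to_query(big, qry)
  scan <- vapply(seq_len(nrow(big)), function(i) {
    any(c(big$tf[i], big$mirna[i], big$target[i]) %in% qry)
  }, logical(1))
  expect_equal(nrow(kept), sum(scan))
})

test_that("co-regulatory network is the union of motif members", {
  net <- ov_network()
  coreg <- build_coreg_network(enumerate_motifs(net), net)
  expect_equal(nrow(coreg$nodes), 3L)
  expect_equal(nrow(coreg$edges), 3L)

  expect_equal(nrow(build_coreg_network(enumerate_motifs(typed_network()),
                                        net)$nodes), 0L)

  # two co-regulatory pairs sharing a target: 5 nodes, not 6
  net2 <- assemble(list(edge_table(c("T1", "T2"), c("g1", "g1"), "TF_GENE"),
                        edge_table(c("hsa-mir-1", "hsa-mir-2"), c("g1", "g1"),
                                   "MIRNA_GENE")), "BOTH")
  m2 <- enumerate_motifs(net2)
  # restrict to the two disjoint-regulator pairs
  m2 <- m2[(m2$tf == "T1" & m2$mirna == "hsa-mir-1") |
             (m2$tf == "T2" & m2$mirna == "hsa-mir-2"), ]
  coreg2 <- build_coreg_network(m2, net2)
  expect_equal(nrow(coreg2$nodes), 5L)
  expect_equal(nrow(coreg2$edges), 4L)
})

test_that("optional flags widen the enumeration as documented", {
  # pairs_include_ffl_triads: the FFL triad is also reported as a pair
  net <- ov_network()
  m <- enumerate_motifs(net, pairs_include_ffl_triads = TRUE)
  expect_equal(sort(m$motif_class), c("COREG_PAIR", "TF_FFL"))

  # allow_tf_targets: a TF may be the joint target
  net2 <- assemble(list(edge_table("T1", "T2", "TF_GENE"),
                        edge_table("hsa-mir-1", "T2", "MIRNA_TF"),
                        edge_table("T2", "g9", "TF_GENE")), "BOTH")
  expect_equal(nrow(enumerate_motifs(net2)), 0L)
  m2 <- enumerate_motifs(net2, allow_tf_targets = TRUE)
  expect_equal(nrow(m2), 1L)
  expect_equal(m2$target, "T2")
  expect_equal(m2$motif_class, "COREG_PAIR")
})
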