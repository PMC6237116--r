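# Readers/writers and the typed-network container.

test_that("edge tables deduplicate, merge evidence, and reject self-loops", {
  tab <- edge_table(c("A", "A", "B", "C"), c("g1", "g1", "g2", "C"),
                    interaction_kind = "TF_GENE",
                    evidence = c("VALIDATED", "PREDICTED", "VALIDATED",
                                 "VALIDATED"))
  expect_equal(nrow(tab), 2L)  # self-loop C->C dropped, A->g1 merged
  expect_equal(tab$evidence[tab$source == "A"], "PREDICTED,VALIDATED")

  # miRNA endpoints deduplicate case-insensitively, first spelling kept
  tab2 <- edge_table(c("hsa-miR-25", "hsa-mir-25"), c("T1", "T1"),
                     interaction_kind = "MIRNA_TF",
                     evidence = c("VALIDATED", "PREDICTED"))
  expect_equal(nrow(tab2), 1L)
  expect_equal(tab2$source, "hsa-miR-25")
  expect_equal(tab2$evidence, "PREDICTED,VALIDATED")
})

test_that("read_edge_table skips malformed rows and reports counts", {
  # fixture: 50 rows = 43 unique well-formed + 5 exact duplicates + 2 malformed
  set.seed(42)
  good <- sprintf("TF%02d\tg%02d", sample(30, 43, TRUE), sample(60, 43, TRUE))
  good <- unique(good)
  dups <- sample(good, 5)
  bad <- c("onlyonefield", "A\tB\tnonsense_evidence")
  lines <- sample(c(good, dups, bad))
  path <- write_lines_tmp(lines)
  tab <- suppressWarnings(read_edge_table(path, "TF_GENE"))
  rep <- attr(tab, "load_report")
  # independent oracle: line scan
  fields <- strsplit(lines, "\t")
  well_formed <- lines[vapply(fields, length, 0L) == 2L]
  expect_equal(nrow(tab), length(unique(well_formed)))
  expect_equal(rep$skipped, 2L)
  expect_equal(rep$rows_in, length(lines))

  expect_error(read_edge_table(tempfile(), "TF_GENE"), "not found")
  empty <- write_lines_tmp(character())
  expect_warning(tab0 <- read_edge_table(empty, "TF_GENE"), "no parseable")
  expect_equal(nrow(tab0), 0L)
})

test_that("per-row evidence overrides the table-level tag", {
  path <- write_lines_tmp(c("A\tg1\tpredicted", "B\tg2", "C\tg3\tvalidated,predicted"))
  tab <- read_edge_table(path, "TF_GENE", evidence = "VALIDATED")
  expect_equal(tab$evidence[tab$source == "A"], "PREDICTED")
  expect_equal(tab$evidence[tab$source == "B"], "VALIDATED")
  expect_equal(tab$evidence[tab$source == "C"], "PREDICTED,VALIDATED")
})

test_that("node lists are trimmed and deduplicated", {
  path <- write_lines_tmp(c("TP53", " PTEN ", "TP53", ""))
  expect_setequal(read_node_list(path), c("TP53", "PTEN"))
  expect_warning(ids <- read_node_list(write_lines_tmp(character())), "empty")
  expect_length(ids, 0L)

  set.seed(1)
  ids <- sprintf("ID%03d", sample(200, 90))
  path <- write_lines_tmp(c(ids, sample(ids, 10)))
  expect_length(read_node_list(path), 90L)
  expect_error(read_node_list(tempfile()), "not found")
})

test_that("GMT parsing matches a line-by-line oracle", {
  path <- write_lines_tmp(c("S1\tdesc\ta\tb\tc", "S2\td2\tx\ty"))
  sets <- read_gmt(path)
  expect_equal(lengths(sets), c(S1 = 3L, S2 = 2L))

  expect_length(read_gmt(write_lines_tmp(character())), 0L)
  expect_warning(sets <- read_gmt(write_lines_tmp(c("S1\tdesc\ta", "SHORT\tx"))),
                 "<3 fields")
  expect_equal(names(sets), "S1")
  expect_error(read_gmt(write_lines_tmp(c("S\td\ta", "S\td\tb"))), "duplicate")

  # 20-set fixture, sizes against an independent parse
  set.seed(3)
  lines <- vapply(1:20, function(i) {
    paste(c(sprintf("SET%02d", i), "na",
            sprintf("m%03d", sample(500, sample(3:15, 1)))), collapse = "\t")
  }, "")
  path <- write_lines_tmp(lines)
  sets <- read_gmt(path)
  expect_length(sets, 20L)
  oracle_sizes <- vapply(strsplit(lines, "\t"),
                         function(f) length(unique(f[-(1:2)])), 0L)
  expect_equal(unname(lengths(sets)), oracle_sizes)
})

test_that("expression matrices are sample-aligned on the intersection", {
  gpath <- tempfile(fileext = ".tsv")
  mpath <- tempfile(fileext = ".tsv")
  set.seed(4)
  gmat <- matrix(rnorm(20 * 30), 20, 30,
                 dimnames = list(sprintf("G%02d", 1:20),
                                 sprintf("s%02d", 1:30)))
  mmat <- matrix(rnorm(10 * 28), 10, 28,
                 dimnames = list(sprintf("hsa-mir-%02d", 1:10),
                                 sprintf("s%02d", 2:29)))
  write_expr_matrix(gmat, gpath)
  write_expr_matrix(mmat, mpath)
  bundle <- read_expression(gpath, mpath)
  expect_length(bundle$samples, 28L)  # independent header comparison
  expect_identical(colnames(bundle$gene), colnames(bundle$mirna))
  expect_identical(colnames(bundle$gene), intersect(colnames(gmat),
                                                    colnames(mmat)))

  # non-numeric cells become NA and are counted; all-missing features dropped
  writeLines(c("feature\ts1\ts2\ts3", "G1\t1.0\toops\t2.0",
               "G2\tbad\tbad\tbad"), gpath)
  writeLines(c("feature\ts1\ts2\ts3", "m1\t1\t2\t3"), mpath)
  b <- read_expression(gpath, mpath)
  expect_equal(b$n_nonnumeric, 4L)
  expect_equal(rownames(b$gene), "G1")

  # zero shared samples is fatal
  writeLines(c("feature\tz1", "G1\t1"), gpath)
  expect_error(read_expression(gpath, mpath), "shared")
})

test_that("network export round-trips through GraphML and JSON", {
  for (fmt in c("GRAPHML", "JSON")) {
    net <- ov_network()
    path <- tempfile(fileext = if (fmt == "JSON") ".json" else ".graphml")
    write_network(net, path, fmt)
    back <- read_network(path)
    expect_equal(back$nodes, net$nodes)
    expect_equal(back$edges, net$edges)

    # empty network writes a valid file with 0 nodes
    e <- typed_network()
    write_network(e, path, fmt)
    expect_equal(nrow(read_network(path)$nodes), 0L)

    # random 60-node network round-trip
    net <- random_typed_network(seed = 11, n_tf = 15, n_mir = 15, n_gene = 30,
                                p = 0.1)
    write_network(net, path, fmt)
    back <- read_network(path)
    expect_equal(back$nodes, net$nodes)
    expect_equal(back$edges, net$edges)
  }
})

test_that("typed_network enforces global class consistency", {
  # TF promotion: X is a gene target and a TF source -> TF everywhere
  net <- assemble(list(edge_table("A", "X", "TF_GENE"),
                       edge_table("X", "g1", "TF_GENE")), "BOTH")
  expect_equal(net$nodes$node_class[net$nodes$id == "X"], "TF")

  # miRNA vs gene conflict is fatal
  expect_error(
    assemble(list(edge_table("A", "weird", "TF_GENE"),
                  edge_table("weird", "g1", "MIRNA_GENE")), "BOTH"),
    "both miRNA and TF/gene")
})
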