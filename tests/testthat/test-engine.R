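test_that("worked queries return exactly the documented answer genes", {
  ex <- nephrogenesis_example()
  idx <- grank_index(ex$graph)

  res1 <- grank_query(ex$graph, ex$annotations, c("Gga.4082", "LHX1"),
                      ex$microarray, index = idx)
  expect_equal(res1$genes, "Ssc.22980")

  res2 <- grank_query(ex$graph, ex$annotations, c("JAG1", "LHX1"),
                      ex$microarray, index = idx)
  expect_setequal(res2$genes, c("Ci-FoxI-c", "FKH-4", "fkh-5"))
  expect_false("Ssc.22980" %in% res2$genes)
  # the organ-development ancestor carries the answer and ranks first
  expect_equal(res2$answers$term[[1]], "GO:0048513")
  expect_equal(res2$answers$genes[[1]], c("Ci-FoxI-c", "FKH-4", "fkh-5"))
})

test_that("repeated runs are byte-identical", {
  ex <- nephrogenesis_example()
  out1 <- write_result(grank_query(ex$graph, ex$annotations,
                                   c("JAG1", "LHX1"), ex$microarray))
  out2 <- write_result(grank_query(ex$graph, ex$annotations,
                                   c("JAG1", "LHX1"), ex$microarray))
  expect_identical(out1, out2)
  js <- write_result(grank_query(ex$graph, ex$annotations,
                                 c("JAG1", "LHX1"), ex$microarray),
                     format = "json")
  expect_identical(js, write_result(grank_query(ex$graph, ex$annotations,
                                                c("JAG1", "LHX1"),
                                                ex$microarray),
                                    format = "json"))
})

test_that("a gene on an isolated term yields an empty answer with a warning", {
  g <- go_graph(data.frame(term = "GO:0000001"))
  ann <- as_go_annotations(data.frame(gene = "solo", term = "GO:0000001"), g)
  expect_warning(res <- grank_query(g, ann, "solo"), "no answer genes")
  expect_equal(res$genes, character())
})

test_that("query genes are excluded from answers unless asked otherwise", {
  ex <- nephrogenesis_example()
  res <- grank_query(ex$graph, ex$annotations, "Ci-FoxI-c", ex$microarray)
  expect_false("Ci-FoxI-c" %in% res$genes)
  expect_true(all(c("FKH-4", "fkh-5") %in% res$genes))

  res_incl <- grank_query(ex$graph, ex$annotations, "Ci-FoxI-c",
                          ex$microarray,
                          grank_params(exclude_query_genes = FALSE))
  expect_true("Ci-FoxI-c" %in% res_incl$genes)
})

test_that("diagnostics expose discarded candidates with witnesses", {
  ex <- nephrogenesis_example()
  res <- grank_query(ex$graph, ex$annotations, c("Gga.4082", "LHX1"),
                     ex$microarray)
  v <- res$diagnostics$verdicts
  discarded <- v[!v$meaningful, ]
  expect_gt(nrow(discarded), 0)
  expect_true(all(!vapply(discarded$witness, is.null, logical(1))))
  expect_true(all(vapply(v$witness[v$meaningful], is.null, logical(1))))
})

test_that("pipeline stages serialise and reload losslessly", {
  ex <- nephrogenesis_example()
  tmp <- withr::local_tempdir()
  obo <- file.path(tmp, "g.obo")
  write_obo(ex$graph, obo)
  g2 <- parse_obo(obo)
  ann_f <- file.path(tmp, "ann.tsv")
  write_annotations(ex$annotations, ann_f)
  ann2 <- parse_annotations(ann_f, "tsv", g2)
  res_disk <- grank_query(g2, ann2, c("Gga.4082", "LHX1"))
  res_mem <- grank_query(ex$graph,
                         as_go_annotations(ex$annotations[, c("gene", "term")],
                                           ex$graph),
                         c("Gga.4082", "LHX1"))
  expect_equal(res_disk$answers$term, res_mem$answers$term)
  expect_equal(res_disk$genes, res_mem$genes)
})
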