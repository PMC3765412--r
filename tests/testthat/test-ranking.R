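test_that("the cumulative hypergeometric score matches exact enumeration", {
  # 55 of the C(10,4) = 210 draws contain at most one annotated gene
  expect_equal(cumulative_hypergeom_score(10, 5, 4, 2), 55 / 210,
               tolerance = 1e-12)
  expect_equal(cumulative_hypergeom_score(10, 5, 4, 0), 0)
  expect_error(cumulative_hypergeom_score(10, 11, 4, 2), "exceed")
  expect_error(cumulative_hypergeom_score(10, 5, 4, 5), "min")
})

test_that("the score agrees with the reference distribution and is monotone", {
  withr::with_seed(99, {
    for (rep in 1:100) {
      a <- sample(20:2000, 1)
      b <- sample(0:a, 1)
      c <- sample(0:a, 1)
      k <- sample(0:min(b, c), 1)
      expect_equal(cumulative_hypergeom_score(a, b, c, k),
                   stats::phyper(k - 1, b, a - b, c),
                   tolerance = 1e-10,
                   info = sprintf("a=%d b=%d c=%d k=%d", a, b, c, k))
    }
  })
  a <- 100; b <- 40; c <- 20
  s <- vapply(0:min(b, c), function(k) cumulative_hypergeom_score(a, b, c, k),
              numeric(1))
  expect_true(all(diff(s) >= 0))
  # at the largest admissible k the sum misses only the topmost support point
  expect_equal(cumulative_hypergeom_score(10, 4, 6, 4),
               1 - stats::dhyper(4, 4, 6, 6), tolerance = 1e-12)
})

test_that("term_score restricts b and k to the microarray universe", {
  ex <- nephrogenesis_example()
  sc <- term_score(ex$microarray, ex$annotations, "GO:0048513")
  expect_equal(sc$a, 50)
  expect_equal(sc$b, 3)       # Ci-FoxI-c, FKH-4, fkh-5
  expect_equal(sc$c, 10)
  expect_equal(sc$k, 3)       # all three are significant
  expect_equal(sc$score,
               cumulative_hypergeom_score(50, 3, 10, 3))
  # unannotated term scores zero
  sc0 <- term_score(ex$microarray, ex$annotations, "GO:0008150")
  expect_equal(sc0$score, 0)
})

test_that("the term-rank formula follows its hand-computed value", {
  g <- go_graph(
    data.frame(term = c("child", "kc", "parent")),
    data.frame(child = c("child", "kc"), parent = c("kc", "parent"),
               relation = "part_of")
  )
  pog <- build_pog(g)
  scores <- tibble::tibble(term = c("child", "kc", "parent"),
                           score = c(0.3, 0.5, 0.8))
  # closure adds child->parent, so Ni(parent) = 2, Ni(kc) = 1
  p <- grank_params(p1 = 0.2, p2 = 0.3)
  expect_equal(kc_rank(pog, "kc", scores, p),
               0.5 * 0.5 + 0.2 * (0.8 / 2) + 0.3 * (0.3 / 1),
               tolerance = 1e-12)

  # default p1 + p2 = 1: the self-score coefficient vanishes
  scores2 <- scores
  scores2$score[scores2$term == "kc"] <- 0.99
  expect_equal(kc_rank(pog, "kc", scores, grank_params()),
               kc_rank(pog, "kc", scores2, grank_params()))

  # isolated node: only the self term survives
  g2 <- go_graph(data.frame(term = "solo"))
  pog2 <- build_pog(g2)
  expect_equal(kc_rank(pog2, "solo", tibble::tibble(term = "solo", score = 0.4),
                       grank_params(p1 = 0.2, p2 = 0.3)),
               0.5 * 0.4)
})

test_that("decay attenuation is exact and monotone", {
  p <- grank_params(decay = 0.7)
  expect_equal(rank_wrt_kc(1, 1, p), 1)
  expect_equal(rank_wrt_kc(1, 2, p), 0.7)
  expect_equal(rank_wrt_kc(2, 3, p), 0.98, tolerance = 1e-12)
  expect_error(rank_wrt_kc(1, 0, p), ">= 1")
  r <- vapply(1:10, function(j) rank_wrt_kc(1.3, j, p), numeric(1))
  expect_true(all(diff(r) <= 0))
})

test_that("rank aggregation supports max and sum", {
  expect_equal(combined_rank(0.5, grank_params()), 0.5)
  expect_equal(combined_rank(0.5, grank_params(aggregation = "sum")), 0.5)
  expect_equal(combined_rank(c(0.2, 0.7, 0.4), grank_params()), 0.7)
  expect_equal(combined_rank(c(0.2, 0.7, 0.4),
                             grank_params(aggregation = "sum")), 1.3)
  expect_error(combined_rank(numeric(0), grank_params()), "empty")
})

test_that("proximity reflects the smallest window and stays in (0, 1]", {
  # layers: r (0); m1, m2 (1); b1, b2 (2) -- window between m2 and b1
  g <- go_graph(
    data.frame(term = c("r", "m1", "m2", "b1", "b2")),
    data.frame(child = c("m1", "m2", "b1", "b2"),
               parent = c("r", "r", "m1", "m1"),
               relation = "is_a")
  )
  d <- assign_depths(g)
  expect_equal(proximity(d, "b1")$prox, 1)             # co-annotation limit
  w <- proximity(d, c("m2", "b1"))
  expect_equal(w$height, 2L)
  expect_equal(w$width, 2L)                            # positions 2 and 1
  expect_equal(w$prox, 1 / 4)

  # two terms three levels apart, adjacent horizontally
  g2 <- go_graph(
    data.frame(term = c("a0", "a1", "a2", "a3", "a4")),
    data.frame(child = c("a1", "a2", "a3", "a4"),
               parent = c("a0", "a1", "a2", "a3"),
               relation = "is_a")
  )
  d2 <- assign_depths(g2)
  w2 <- proximity(d2, c("a2", "a4"))
  expect_equal(w2$height, 3L)
  expect_equal(w2$width, 1L)
  expect_equal(w2$prox, 1 / 3)

  sim <- simulate_ontology(40, seed = 12)
  dsim <- quiet_depths(sim)
  withr::with_seed(13, {
    for (rep in 1:100) {
      ts <- sample(sim$terms$term, sample(1:6, 1))
      pr <- proximity(dsim, ts)$prox
      expect_gt(pr, 0)
      expect_lte(pr, 1)
    }
  })
})

test_that("overall scores collapse to summed term ranks in the limit", {
  # two genes co-annotated to one term, decay irrelevant, prox = 1
  g <- go_graph(
    data.frame(term = c("root", "t")),
    data.frame(child = "t", parent = "root", relation = "part_of")
  )
  ann <- as_go_annotations(
    data.frame(gene = c("g1", "g2", "g3"), term = "t"), g)
  p <- grank_params(decay = 1, p1 = 0.2, p2 = 0.3,
                    exclude_query_genes = FALSE)
  res <- suppressWarnings(grank_query(g, ann, c("g1", "g2"), params = p))
  pog <- build_pog(g)
  scores <- tibble::tibble(term = c("root", "t"), score = c(1, 1))
  expected <- 2 * kc_rank(pog, "t", scores, p)
  expect_equal(res$answers$score[res$answers$term == "t"],
               rep(expected, sum(res$answers$term == "t")))
})

test_that("overall scores are invariant under query gene order", {
  ex <- nephrogenesis_example()
  r1 <- grank_query(ex$graph, ex$annotations, c("JAG1", "LHX1"),
                    ex$microarray)
  r2 <- grank_query(ex$graph, ex$annotations, c("LHX1", "JAG1"),
                    ex$microarray)
  expect_equal(r1$answers$score, r2$answers$score)
  expect_equal(r1$answers$term, r2$answers$term)
  expect_true(all(diff(r1$answers$score) <= 0))
  expect_true(all(is.finite(r1$answers$score)) && all(r1$answers$score >= 0))
})
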