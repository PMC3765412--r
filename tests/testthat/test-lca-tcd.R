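example_index <- function() {
  ex <- nephrogenesis_example()
  list(ex = ex, pog = build_pog(ex$graph), d = assign_depths(ex$graph))
}

test_that("documented LCA/TCD memberships hold on the example", {
  z <- example_index()
  expect_true("GO:0072009" %in%
                lowest_common_ancestors(z$pog, c("GO:0072088", "GO:0072077")))
  expect_true("GO:0072283" %in%
                top_common_descendants(z$pog, c("GO:0072006", "GO:0072088")))
  # a single term is its own LCA and TCD
  expect_equal(lowest_common_ancestors(z$pog, "GO:0072006"), "GO:0072006")
  expect_equal(top_common_descendants(z$pog, "GO:0072006"), "GO:0072006")
  # two disjoint part-of chains share nothing
  g <- go_graph(data.frame(term = c("A", "B", "X", "Y")),
                data.frame(child = c("B", "Y"), parent = c("A", "X"),
                           relation = "part_of"))
  p <- build_pog(g)
  expect_equal(top_common_descendants(p, c("A", "X")), character())
  expect_equal(lowest_common_ancestors(p, c("B", "Y")), character())
})

test_that("LCA/TCD enumeration matches the exhaustive set oracle", {
  withr::with_seed(202, {
    for (rep in 1:40) {
      g <- random_typed_dag(sample(5:10, 1))
      pog <- build_pog(g)
      kcs <- sample(g$terms$term, 2)
      up_cl <- lapply(kcs, function(t) c(t, pog_ancestors(pog, t)))
      common <- Reduce(intersect, up_cl)
      lca_oracle <- sort(Filter(function(a) {
        !any(pog_descendants(pog, a) %in% common)
      }, common))
      expect_equal(lowest_common_ancestors(pog, kcs), lca_oracle)

      down_cl <- lapply(kcs, function(t) c(t, pog_descendants(pog, t)))
      common_d <- Reduce(intersect, down_cl)
      tcd_oracle <- sort(Filter(function(a) {
        !any(pog_ancestors(pog, a) %in% common_d)
      }, common_d))
      expect_equal(top_common_descendants(pog, kcs), tcd_oracle)
    }
  })
})

test_that("documented verdicts hold with their witnesses", {
  z <- example_index()
  v1 <- is_meaningful(z$pog, z$d, c("GO:0072088", "GO:0072077"),
                      "GO:0072009", "lca")
  expect_false(v1$meaningful)
  expect_equal(v1$witness$type, "depth_equality")
  expect_equal(v1$witness$kc, "GO:0072077")

  v2 <- is_meaningful(z$pog, z$d, c("GO:0072006", "GO:0072088"),
                      "GO:0048513", "lca")
  expect_false(v2$meaningful)
  expect_equal(v2$witness$type, "path")
  expect_setequal(v2$witness$pair, c("GO:0072073", "GO:0072088"))

  v3 <- is_meaningful(z$pog, z$d, c("GO:0072006", "GO:0072009"),
                      "GO:0048513", "lca")
  expect_true(v3$meaningful)
  expect_null(v3$witness)

  v4 <- is_meaningful(z$pog, z$d, c("GO:0072006", "GO:0072009"),
                      "GO:0072283", "tcd")
  expect_false(v4$meaningful)
  expect_setequal(v4$witness$pair, c("GO:0072009", "GO:0072077"))

  expect_error(
    is_meaningful(z$pog, z$d, c("GO:0072006", "GO:0072009"),
                  "GO:0009887", "lca"),
    "not a common"
  )
})

test_that("meaningfulness equals the exhaustive path-depth oracle", {
  withr::with_seed(303, {
    checked <- 0
    rep <- 0
    while (checked < 200 && rep < 400) {
      rep <- rep + 1
      g <- random_typed_dag(sample(6:12, 1), p_edge = runif(1, 0.25, 0.5))
      pog <- build_pog(g)
      d <- quiet_depths(g)
      kcs <- sample(g$terms$term, sample(2:3, 1))
      for (role in c("lca", "tcd")) {
        cands <- if (role == "lca") lowest_common_ancestors(pog, kcs)
        else top_common_descendants(pog, kcs)
        for (cand in cands) {
          expect_equal(
            is_meaningful(pog, d, kcs, cand, role)$meaningful,
            oracle_meaningful(pog, d, kcs, cand, role),
            info = paste("rep", rep, role, cand)
          )
          checked <- checked + 1
        }
      }
    }
    expect_gte(checked, 200)
  })
})

test_that("TCD verdicts equal LCA verdicts on the edge-reversed POG", {
  withr::with_seed(404, {
    for (rep in 1:20) {
      g <- random_typed_dag(8)
      pog <- build_pog(g)
      d <- quiet_depths(g)
      rev_pog <- pog
      rev_pog$edges <- tibble::tibble(child = pog$edges$parent,
                                      parent = pog$edges$child,
                                      provenance = pog$edges$provenance)
      kcs <- sample(g$terms$term, 2)
      for (cand in top_common_descendants(pog, kcs)) {
        expect_equal(
          is_meaningful(pog, d, kcs, cand, "tcd")$meaningful,
          is_meaningful(rev_pog, d, kcs, cand, "lca")$meaningful
        )
      }
    }
  })
})

test_that("verdicts are invariant to keyword-context order", {
  z <- example_index()
  kcs <- c("GO:0072006", "GO:0072009")
  for (perm in list(kcs, rev(kcs))) {
    expect_true(is_meaningful(z$pog, z$d, perm, "GO:0048513", "lca")$meaningful)
    expect_false(is_meaningful(z$pog, z$d, perm, "GO:0072283", "tcd")$meaningful)
  }
})

test_that("clean chains with distinct depths are always meaningful", {
  # A <- B <- C (part-of), depths 0,1,2 via parallel is-a edges
  g <- go_graph(
    data.frame(term = c("A", "B", "C")),
    data.frame(child = c("B", "C", "B", "C"),
               parent = c("A", "B", "A", "B"),
               relation = c("is_a", "is_a", "part_of", "part_of"))
  )
  pog <- build_pog(g)
  d <- assign_depths(g)
  expect_true(is_meaningful(pog, d, c("C"), "A", "lca")$meaningful)
  expect_true(is_meaningful(pog, d, c("B", "C"), "A", "lca")$meaningful)
})

test_that("existential path semantics accepts one clean route", {
  # candidate A above kc D; one route climbs through the equal-depth pair
  # E1/E2, another clean route exists; universal semantics rejects,
  # existential accepts
  g <- go_graph(
    data.frame(term = c("A", "E1", "E2", "D")),
    rbind(
      data.frame(child = c("E1", "E2"), parent = "A", relation = "is_a"),
      data.frame(child = "D", parent = "E1", relation = "is_a"),
      data.frame(child = "D", parent = "E1", relation = "part_of"),
      data.frame(child = "E1", parent = "E2", relation = "part_of"),
      data.frame(child = "E2", parent = "A", relation = "part_of")
    )
  )
  pog <- build_pog(g)
  d <- assign_depths(g)
  expect_false(is_meaningful(pog, d, "D", "A", "lca", "all")$meaningful)
  expect_true(is_meaningful(pog, d, "D", "A", "lca", "exists")$meaningful)
})

test_that("candidate enumeration over per-gene combinations matches the examples", {
  z <- example_index()
  kcs <- map_query_to_kcs(c("Gga.4082", "LHX1"), z$ex$annotations)
  verdicts <- meaningful_candidates(z$pog, z$d, kcs)
  row <- function(v, term, role) v[v$candidate == term & v$role == role, ]
  expect_true(row(verdicts, "GO:0072283", "tcd")$meaningful)
  expect_false(row(verdicts, "GO:0048513", "lca")$meaningful)
  expect_false(row(verdicts, "GO:0072009", "lca")$meaningful)

  kcs2 <- map_query_to_kcs(c("JAG1", "LHX1"), z$ex$annotations)
  verdicts2 <- meaningful_candidates(z$pog, z$d, kcs2)
  expect_true(row(verdicts2, "GO:0048513", "lca")$meaningful)
  expect_false(row(verdicts2, "GO:0072283", "tcd")$meaningful)

  # degenerate single-gene single-term query: the term is its own
  # trivially meaningful LCA and TCD
  kcs3 <- map_query_to_kcs("Gga.4082", z$ex$annotations)
  v3 <- meaningful_candidates(z$pog, z$d, kcs3)
  expect_true(all(v3$meaningful[v3$candidate == "GO:0072088"]))
  expect_setequal(v3$role[v3$candidate == "GO:0072088"], c("lca", "tcd"))
})
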