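#' Simulate a layered random ontology
#'
#' Generates a random typed DAG for property testing.  Terms are arranged
#' in layers `0..max_depth`; every non-root term gets one is-a parent in
#' the layer directly above (so its longest is-a distance to the root
#' equals its layer), plus extra is-a parents in any higher layer with
#' probability `is_a_density` per candidate layer, and random part-of
#' edges towards higher layers covering about `part_of_fraction` of the
#' terms.  All draws are governed by `seed`; the same seed reproduces the
#' same graph.
#'
#' @param n_terms Number of terms (>= 2).
#' @param is_a_density Probability of an extra is-a parent per higher
#'   layer, in `[0, 1]`.
#' @param part_of_fraction Fraction of terms receiving a part-of parent,
#'   in `[0, 1]`.
#' @param max_depth Deepest layer (>= 1).
#' @param seed Integer seed.
#' @return A [go_graph()].
#' @examples
#' simulate_ontology(12, seed = 1)
#' @export
simulate_ontology <- function(n_terms, is_a_density = 0.15,
                              part_of_fraction = 0.3, max_depth = 5,
                              seed = 1) {
  if (n_terms < 2) abort("`n_terms` must be at least 2.")
  if (max_depth < 1) abort("`max_depth` must be at least 1.")
  for (p in c(is_a_density, part_of_fraction)) {
    if (p < 0 || p > 1) abort("Densities must lie in [0, 1].")
  }
  withr::with_seed(seed, {
    ids <- sprintf("T%04d", seq_len(n_terms))
    # layer 0 is the single root; remaining terms spread over 1..max_depth,
    # with the first max_depth of them pinned one per layer so every layer
    # is populated when n_terms allows
    n_rest <- n_terms - 1L
    depth_levels <- seq_len(max_depth)
    layer <- c(0L, head(depth_levels, n_rest),
               if (n_rest > max_depth)
                 sample(depth_levels, n_rest - max_depth, replace = TRUE))
    terms <- tibble(term = ids, name = ids, namespace = "simulated")

    edges <- list()
    for (i in seq_along(ids)[-1]) {
      l <- layer[[i]]
      above <- ids[layer == l - 1L]
      primary <- if (length(above) == 1) above else sample(above, 1)
      parents <- primary
      higher <- which(layer < l - 1L)
      if (length(higher) > 0 && is_a_density > 0) {
        extra <- higher[stats::runif(length(higher)) < is_a_density]
        parents <- c(parents, ids[extra])
      }
      edges[[length(edges) + 1L]] <- tibble(child = ids[[i]],
                                            parent = unique(parents),
                                            relation = "is_a")
    }
    n_po <- round(part_of_fraction * n_terms)
    if (n_po > 0) {
      lower <- which(layer > 0L)
      picks <- sample(lower, min(n_po, length(lower)))
      for (i in picks) {
        cand <- which(layer < layer[[i]])
        j <- if (length(cand) == 1) cand else sample(cand, 1)
        edges[[length(edges) + 1L]] <- tibble(child = ids[[i]],
                                              parent = ids[[j]],
                                              relation = "part_of")
      }
    }
    go_graph(terms, distinct(bind_rows(edges)))
  })
}

#' Simulate gene annotations over an ontology
#'
#' Draws, for each gene, a Poisson-distributed number of annotation terms
#' (at least one) uniformly over the graph's terms.
#'
#' @param graph A [go_graph()].
#' @param n_genes Number of genes.
#' @param mean_terms_per_gene Mean annotations per gene (>= 1).
#' @param seed Integer seed.
#' @return A `go_annotations` tibble with genes `G0001`, `G0002`, ...
#' @export
simulate_annotations <- function(graph, n_genes, mean_terms_per_gene = 2,
                                 seed = 1) {
  stopifnot(inherits(graph, "go_graph"))
  if (n_genes < 1) abort("`n_genes` must be positive.")
  if (mean_terms_per_gene < 1) abort("`mean_terms_per_gene` must be >= 1.")
  withr::with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    rows <- lapply(genes, function(g) {
      k <- 1L + stats::rpois(1, mean_terms_per_gene - 1)
      tibble(gene = g,
             term = sample(graph$terms$term, min(k, nrow(graph$terms))))
    })
    as_go_annotations(bind_rows(rows), graph)
  })
}

#' Simulate a microarray reference
#'
#' Flags each gene significant independently with probability
#' `significant_fraction`.
#'
#' @param genes Character vector: the gene universe.
#' @param significant_fraction Bernoulli success probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A `go_microarray` tibble.
#' @export
simulate_microarray <- function(genes, significant_fraction = 0.1,
                                seed = 1) {
  if (significant_fraction < 0 || significant_fraction > 1) {
    abort("`significant_fraction` must lie in [0, 1].")
  }
  genes <- unique(as.character(genes))
  withr::with_seed(seed, {
    as_go_microarray(genes,
                     stats::runif(length(genes)) < significant_fraction)
  })
}
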