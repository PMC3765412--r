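#' Ranking and search parameters
#'
#' Bundles the tunable parameters of the search engine.  The defaults are the
#' ones used throughout the package's documentation and examples: a decay of
#' 0.7 per hierarchical level, and navigation probabilities `p1 = 0.4`
#' (stepping from an annotation term to one of its parents) and `p2 = 0.6`
#' (stepping from a neighbour back down to the annotation term).  Note that
#' with the default `p1 + p2 = 1` the self-score coefficient `1 - p1 - p2`
#' of the term-rank formula is exactly zero, so a term's rank is driven
#' entirely by its part-of neighbourhood.
#'
#' @param decay Attenuation per hierarchical level separating a candidate
#'   term from an annotation term, in `(0, 1]`.
#' @param p1 Probability of navigating from an annotation term up to a
#'   parent term, in `[0, 1]`.
#' @param p2 Probability of navigating from a neighbour term down to the
#'   annotation term, in `[0, 1]`.  `p1 + p2` must not exceed 1.
#' @param aggregation How ranks across the several annotation terms of one
#'   gene are combined: `"max"` (default) or `"sum"`.
#' @param exclude_query_genes Drop the query's own genes from answers
#'   (default `TRUE`).
#' @param iea_filter Drop annotations with evidence code `"IEA"` before
#'   mapping queries (default `FALSE`).
#' @param path_semantics `"all"` (default): a candidate is meaningful with
#'   respect to an annotation term only if *every* part-of-graph path
#'   between them is free of depth repeats; `"exists"`: one clean path
#'   suffices.
#' @param partof_transitive Include plain part-of-over-part-of transitivity
#'   when inferring part-of edges (default `TRUE`); `FALSE` restricts
#'   inference to single part-of edges wrapped in is-a chains.
#' @param kcrank_graph Graph supplying the neighbourhood of the term-rank
#'   formula: `"pog"` (default, the part-of graph) or `"go"` (the raw
#'   ontology graph, both relation types).
#'
#' @return A list of class `grank_params`.
#' @examples
#' grank_params()
#' grank_params(decay = 1, aggregation = "sum")
#' @export
grank_params <- function(decay = 0.7,
                         p1 = 0.4,
                         p2 = 0.6,
                         aggregation = c("max", "sum"),
                         exclude_query_genes = TRUE,
                         iea_filter = FALSE,
                         path_semantics = c("all", "exists"),
                         partof_transitive = TRUE,
                         kcrank_graph = c("pog", "go")) {
  aggregation <- match.arg(aggregation)
  path_semantics <- match.arg(path_semantics)
  kcrank_graph <- match.arg(kcrank_graph)
  if (!is.numeric(decay) || length(decay) != 1 || decay <= 0 || decay > 1) {
    abort("`decay` must be a single number in (0, 1].")
  }
  for (p in list(p1 = p1, p2 = p2)) {
    if (!is.numeric(p) || length(p) != 1 || p < 0 || p > 1) {
      abort("`p1` and `p2` must be single numbers in [0, 1].")
    }
  }
  if (p1 + p2 > 1 + 1e-12) {
    abort("`p1 + p2` must not exceed 1.")
  }
  structure(
    list(
      decay = decay, p1 = p1, p2 = p2, aggregation = aggregation,
      exclude_query_genes = isTRUE(exclude_query_genes),
      iea_filter = isTRUE(iea_filter),
      path_semantics = path_semantics,
      partof_transitive = isTRUE(partof_transitive),
      kcrank_graph = kcrank_graph
    ),
    class = "grank_params"
  )
}

#' @export
print.grank_params <- function(x, ...) {
  cat("<grank_params>\n")
  cat(sprintf("  decay = %g, p1 = %g, p2 = %g, aggregation = %s\n",
              x$decay, x$p1, x$p2, x$aggregation))
  cat(sprintf("  exclude_query_genes = %s, iea_filter = %s\n",
              x$exclude_query_genes, x$iea_filter))
  cat(sprintf("  path_semantics = %s, partof_transitive = %s, kcrank_graph = %s\n",
              x$path_semantics, x$partof_transitive, x$kcrank_graph))
  invisible(x)
}
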