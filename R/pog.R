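#' Build the part-of graph (POG)
#'
#' Converts an ontology graph into its part-of graph: the same node set,
#' with an edge `child part-of parent` wherever the ontology states the
#' relation explicitly or it can be inferred.  Two inference rules drive
#' the derivation: if A is-a B and B part-of C then A part-of C, and if
#' A part-of B and B is-a C then A part-of C.  By default part-of is also
#' treated as transitive, so chains mixing both relation types collapse;
#' `partof_transitive = FALSE` restricts inference to a single part-of edge
#' wrapped in is-a chains (the strict reading of the two rules).  The edge
#' set is the least fixed point of the rules; every explicit part-of edge
#' is retained, is-a edges are absent, and nodes without part-of relations
#' are kept as isolated nodes.
#'
#' @param graph A [go_graph()].
#' @param partof_transitive Include part-of-over-part-of transitivity
#'   (default `TRUE`).
#' @return A list of class `go_pog` with tibbles `terms` and `edges`
#'   (`child`, `parent`, `provenance` in `{"explicit", "inferred"}`).
#' @examples
#' g <- go_graph(
#'   data.frame(term = c("A", "B", "C")),
#'   data.frame(child = c("C", "B"), parent = c("B", "A"),
#'              relation = c("part_of", "is_a"))
#' )
#' build_pog(g)$edges   # C part-of B (explicit), C part-of A (inferred)
#' @export
build_pog <- function(graph, partof_transitive = TRUE) {
  stopifnot(inherits(graph, "go_graph"))
  terms <- graph$terms$term
  edges <- graph$edges
  explicit <- edges[edges$relation == "part_of", c("child", "parent")]

  closure <- if (nrow(edges) == 0 || nrow(explicit) == 0) {
    tibble(child = character(), parent = character())
  } else {
    partof_closure(terms, edges, partof_transitive)
  }

  pog_edges <- closure |>
    mutate(provenance = ifelse(
      paste(.data$child, .data$parent) %in%
        paste(explicit$child, explicit$parent),
      "explicit", "inferred"
    )) |>
    arrange(.data$child, .data$parent)

  # Inference over a DAG cannot create a cycle; assert the invariant anyway.
  if (nrow(pog_edges) > 0) {
    ig <- igraph::graph_from_data_frame(pog_edges[, 1:2], directed = TRUE,
                                        vertices = terms)
    if (!igraph::is_dag(ig)) {
      abort("Internal error: part-of closure introduced a cycle.")
    }
  }

  structure(
    list(terms = graph$terms, edges = pog_edges,
         partof_transitive = isTRUE(partof_transitive)),
    class = "go_pog"
  )
}

# Part-of reachability on a doubled graph.  State 0 = no part-of edge used
# yet, state 1 = at least one used.  In transitive mode any walk with >= 1
# part-of edge yields a part-of conclusion; in strict mode the walk must be
# is-a*, one part-of, is-a* (no second part-of once in state 1).
partof_closure <- function(terms, edges, partof_transitive) {
  v0 <- paste0(terms, "\r0")
  v1 <- paste0(terms, "\r1")
  isa <- edges[edges$relation == "is_a", , drop = FALSE]
  po <- edges[edges$relation == "part_of", , drop = FALSE]
  from <- c(paste0(isa$child, "\r0", recycle0 = TRUE),
            paste0(isa$child, "\r1", recycle0 = TRUE),
            paste0(po$child, "\r0", recycle0 = TRUE))
  to <- c(paste0(isa$parent, "\r0", recycle0 = TRUE),
          paste0(isa$parent, "\r1", recycle0 = TRUE),
          paste0(po$parent, "\r1", recycle0 = TRUE))
  if (partof_transitive) {
    from <- c(from, paste0(po$child, "\r1", recycle0 = TRUE))
    to <- c(to, paste0(po$parent, "\r1", recycle0 = TRUE))
  }
  ig <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to), directed = TRUE,
    vertices = c(v0, v1)
  )
  d <- igraph::distances(ig, v = v0, to = v1, mode = "out")
  reach <- is.finite(d)
  idx <- which(reach, arr.ind = TRUE)
  out <- tibble(child = terms[idx[, 1]], parent = terms[idx[, 2]])
  out[out$child != out$parent, ]
}

#' @export
print.go_pog <- function(x, ...) {
  cat(sprintf("<go_pog> %d terms, %d part-of edges (%d explicit, %d inferred)\n",
              nrow(x$terms), nrow(x$edges),
              sum(x$edges$provenance == "explicit"),
              sum(x$edges$provenance == "inferred")))
  invisible(x)
}

#' Ancestors and descendants in the part-of graph
#'
#' All nodes reachable from `term` by following part-of edges upward
#' (`pog_ancestors()`) or downward (`pog_descendants()`); the term itself
#' is excluded.
#'
#' @param pog A [build_pog()] result.
#' @param term A term identifier present in the POG.
#' @return A character vector of term identifiers, lexicographically
#'   sorted.
#' @export
pog_ancestors <- function(pog, term) {
  pog_reach(pog, term, up = TRUE)
}

#' @rdname pog_ancestors
#' @export
pog_descendants <- function(pog, term) {
  pog_reach(pog, term, up = FALSE)
}

pog_reach <- function(pog, term, up) {
  stopifnot(inherits(pog, "go_pog"))
  if (!term %in% pog$terms$term) {
    abort(paste0("Unknown term: ", term))
  }
  edges <- pog$edges
  adj <- if (up) split(edges$parent, edges$child) else split(edges$child, edges$parent)
  seen <- character()
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, c(seen, term))
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  sort(seen)
}

#' Export a part-of graph as TSV
#'
#' Writes the POG edge list as a 3-column tab-separated table
#' (`child`, `parent`, `provenance`) for inspection.
#'
#' @param pog A [build_pog()] result.
#' @param file Optional path; if omitted the lines are returned invisibly.
#' @return The TSV lines, invisibly.
#' @export
write_pog <- function(pog, file = NULL) {
  stopifnot(inherits(pog, "go_pog"))
  lines <- c("child\tparent\tprovenance",
             sprintf("%s\t%s\t%s", pog$edges$child, pog$edges$parent,
                     pog$edges$provenance))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
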