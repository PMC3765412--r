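#' Recall and precision of an answer gene set
#'
#' Given the `m` genes retrieved by a method and the `n` genes of a
#' reference set (e.g. a pathway), recall is the fraction of the reference
#' recovered and precision the fraction of the answer that belongs to the
#' reference.  An empty answer leaves precision undefined (`NA` with a
#' warning); an empty reference set is an error.
#'
#' @param answer_genes Character vector: genes retrieved.
#' @param pathway_genes Non-empty character vector: the reference set.
#' @return A one-row tibble with columns `n`, `m`, `n_overlap`, `recall`,
#'   `precision`.
#' @examples
#' recall_precision(c("a", "b", "c", "d"), c("b", "c", "e"))
#' @export
recall_precision <- function(answer_genes, pathway_genes) {
  pathway_genes <- unique(as.character(pathway_genes))
  if (length(pathway_genes) == 0) abort("Reference gene set must be non-empty.")
  answer_genes <- unique(as.character(answer_genes))
  n <- length(pathway_genes)
  m <- length(answer_genes)
  overlap <- length(intersect(answer_genes, pathway_genes))
  precision <- if (m == 0) {
    warn("Empty answer set: precision is undefined.")
    NA_real_
  } else {
    overlap / m
  }
  tibble(n = n, m = m, n_overlap = overlap,
         recall = overlap / n, precision = precision)
}

#' Classify an ontology/query configuration
#'
#' Labels a set of keyword contexts along two axes.  The relation
#' criterion inspects the edges on all upward routes from each keyword
#' context: 1 when every one connects to its ancestors by is-a relations
#' only, 2 when by part-of only, 3 when both types occur.  The level
#' criterion uses the is-a depths: 4 when all keyword contexts sit in
#' shallow levels (depth below six), 5 when all sit at depth six or
#' deeper, 6 when mixed.
#'
#' @param graph A [go_graph()].
#' @param depths An [assign_depths()] result.
#' @param kcs Character vector of keyword contexts present in the graph.
#' @return A one-row tibble with columns `relation_criterion` (1-3) and
#'   `level_criterion` (4-6).
#' @export
classify_criterion <- function(graph, depths, kcs) {
  stopifnot(inherits(graph, "go_graph"), inherits(depths, "go_depths"))
  kcs <- unique(as.character(kcs))
  unknown <- setdiff(kcs, graph$terms$term)
  if (length(unknown) > 0) {
    abort(paste0("Unknown keyword context(s): ", paste(unknown, collapse = ", ")))
  }

  # relation types on edges reachable upward from each keyword context
  edges <- graph$edges
  adj <- split(seq_len(nrow(edges)), edges$child)
  used <- character()
  for (kc in kcs) {
    frontier <- kc
    seen <- character()
    while (length(frontier) > 0) {
      eidx <- unlist(adj[frontier], use.names = FALSE)
      if (length(eidx) > 0) used <- union(used, edges$relation[eidx])
      nxt <- setdiff(unique(edges$parent[eidx]), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
  }
  relation <- if (setequal(used, "is_a") || length(used) == 0) 1L
  else if (setequal(used, "part_of")) 2L
  else 3L

  dmap <- setNames(depths$depth, depths$term)
  dk <- dmap[kcs]
  level <- if (all(dk < 6)) 4L else if (all(dk >= 6)) 5L else 6L

  tibble(relation_criterion = relation, level_criterion = level)
}
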