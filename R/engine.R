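#' Precompute the search index of an ontology
#'
#' The part-of graph and the depth map depend only on the ontology, so for
#' repeated queries they are computed once and reused.
#'
#' @param graph A [go_graph()].
#' @param params A [grank_params()] (supplies `partof_transitive`).
#' @return A list of class `grank_index` with elements `graph`, `pog`,
#'   `depths`.
#' @export
grank_index <- function(graph, params = grank_params()) {
  stopifnot(inherits(graph, "go_graph"))
  structure(
    list(
      graph = graph,
      pog = build_pog(graph, partof_transitive = params$partof_transitive),
      depths = assign_depths(graph)
    ),
    class = "grank_index"
  )
}

#' Answer a gene query
#'
#' Runs the full pipeline: maps the query genes to their annotation terms,
#' enumerates lowest common ancestors and top common descendants over the
#' part-of graph, screens them with the depth-uniqueness rule, ranks the
#' meaningful ones, and converts them back to genes via direct annotation.
#' LCA- and TCD-derived answers are interleaved in one ranking, each row
#' tagged with its role.  Identical inputs produce identical output.
#'
#' @param graph A [go_graph()].
#' @param annotations A [parse_annotations()] result.
#' @param genes Character vector of query gene identifiers.
#' @param microarray Optional [parse_microarray()] reference driving the
#'   term scores; when `NULL` every term scores 1, so ranking reflects
#'   decay and proximity only.
#' @param params A [grank_params()].
#' @param index Optional precomputed [grank_index()] for `graph`.
#' @return A list of class `grank_result` with elements `query`, `answers`
#'   (a `grank_ranking` tibble), `genes` (the answer genes in rank order)
#'   and `diagnostics` (keyword contexts, all candidate verdicts including
#'   the discarded ones with their witnesses, and the proximity window).
#' @examples
#' ex <- nephrogenesis_example()
#' res <- grank_query(ex$graph, ex$annotations, c("Gga.4082", "LHX1"),
#'                    ex$microarray)
#' res$genes
#' @export
grank_query <- function(graph, annotations, genes, microarray = NULL,
                        params = grank_params(), index = NULL) {
  stopifnot(inherits(graph, "go_graph"), inherits(annotations, "go_annotations"))
  if (is.null(index)) index <- grank_index(graph, params)
  stopifnot(inherits(index, "grank_index"))

  kcs <- map_query_to_kcs(genes, annotations, params)
  verdicts <- meaningful_candidates(index$pog, index$depths, kcs,
                                    semantics = params$path_semantics)

  kc_terms <- sort(unique(kcs$term))
  neighbour_terms <- unique(c(
    kc_terms,
    index$pog$edges$parent[index$pog$edges$child %in% kc_terms],
    index$pog$edges$child[index$pog$edges$parent %in% kc_terms],
    graph$edges$parent[graph$edges$child %in% kc_terms],
    graph$edges$child[graph$edges$parent %in% kc_terms]
  ))
  scores <- if (is.null(microarray)) {
    tibble(term = neighbour_terms, score = 1)
  } else {
    term_score(microarray, annotations, neighbour_terms)
  }

  answers <- if (any(verdicts$meaningful)) {
    rank_answers(verdicts, kcs, index$pog, index$depths, scores,
                 annotations, params, graph)
  } else {
    warn("No meaningful candidate term for this query.")
    empty_ranking()
  }

  answer_genes <- unique(unlist(answers$genes, use.names = FALSE)) %||% character()
  if (length(answer_genes) == 0 && nrow(answers) > 0) {
    warn("Query produced no answer genes (no other gene is annotated to a meaningful term).")
  }
  structure(
    list(
      query = unique(as.character(genes)),
      answers = answers,
      genes = answer_genes,
      diagnostics = list(
        kcs = kcs,
        verdicts = verdicts,
        n_meaningful = sum(verdicts$meaningful),
        n_candidates = nrow(verdicts),
        prox = attr(answers, "prox"),
        unannotated = attr(kcs, "unannotated"),
        params = params
      )
    ),
    class = "grank_result"
  )
}

#' @export
print.grank_result <- function(x, ...) {
  cat(sprintf("<grank_result> query: %s\n", paste(x$query, collapse = ", ")))
  d <- x$diagnostics
  cat(sprintf("  %d keyword context(s); %d candidate(s), %d meaningful\n",
              nrow(d$kcs), d$n_candidates, d$n_meaningful))
  if (nrow(x$answers) == 0) {
    cat("  no answers\n")
  } else {
    cat(sprintf("  %d ranked term(s); answer genes: %s\n",
                nrow(x$answers), paste(x$genes, collapse = ", ")))
  }
  invisible(x)
}

#' Export a ranking as TSV or JSON
#'
#' The TSV has columns `rank`, `term`, `role`, `score` and comma-joined
#' `genes`; the JSON variant additionally carries the proximity factor.
#'
#' @param result A [grank_query()] result.
#' @param file Optional path.
#' @param format `"tsv"` or `"json"`.
#' @return The serialised lines (TSV) or JSON string, invisibly.
#' @export
write_result <- function(result, file = NULL, format = c("tsv", "json")) {
  format <- match.arg(format)
  stopifnot(inherits(result, "grank_result"))
  a <- result$answers
  if (format == "tsv") {
    out <- c("rank\tterm\trole\tscore\tgenes",
             sprintf("%d\t%s\t%s\t%.10g\t%s", a$rank, a$term, a$role, a$score,
                     vapply(a$genes, paste, character(1), collapse = ",")))
  } else {
    out <- jsonlite::toJSON(
      list(
        query = result$query,
        prox = result$diagnostics$prox,
        answers = lapply(seq_len(nrow(a)), function(i) {
          list(rank = a$rank[[i]], term = a$term[[i]], role = a$role[[i]],
               score = a$score[[i]], genes = a$genes[[i]])
        })
      ),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
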