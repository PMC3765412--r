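#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a query result
#'
#' Returns one row per (term, gene) answer pair, with the term's rank,
#' role and score repeated along its genes; terms without answer genes
#' keep one row with `gene = NA`.
#'
#' @param x A [grank_query()] result.
#' @param ... Unused.
#' @return A tibble with columns `rank`, `term`, `role`, `score`, `gene`.
#' @export
tidy.grank_result <- function(x, ...) {
  a <- as_tibble(x$answers)
  if (nrow(a) == 0) {
    return(tibble(rank = integer(), term = character(), role = character(),
                  score = numeric(), gene = character()))
  }
  a |>
    mutate(gene = lapply(.data$genes, function(g) {
      if (length(g) == 0) NA_character_ else g
    })) |>
    select("rank", "term", "role", "score", "gene") |>
    tidyr::unnest("gene")
}

#' Summarise a query result in one row
#'
#' @param x A [grank_query()] result.
#' @param ... Unused.
#' @return A one-row tibble: query size, numbers of keyword contexts,
#'   candidates and meaningful candidates, answer terms and genes, the
#'   proximity factor and the top score.
#' @export
glance.grank_result <- function(x, ...) {
  d <- x$diagnostics
  tibble(
    n_query_genes = length(x$query),
    n_kcs = nrow(d$kcs),
    n_candidates = d$n_candidates,
    n_meaningful = d$n_meaningful,
    n_answer_terms = nrow(x$answers),
    n_answer_genes = length(x$genes),
    prox = d$prox %||% NA_real_,
    top_score = if (nrow(x$answers) > 0) max(x$answers$score) else NA_real_
  )
}

#' Plot the ranked terms of a query result
#'
#' A horizontal bar chart of candidate scores, coloured by role (common
#' ancestor vs common descendant).
#'
#' @param object A [grank_query()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.grank_result <- function(object, ...) {
  a <- as_tibble(object$answers)
  if (nrow(a) == 0) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no answers") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(a, ggplot2::aes(
    x = .data$score,
    y = stats::reorder(.data$term, .data$score),
    fill = .data$role
  )) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "score", y = NULL, fill = "role",
                  title = paste("Query:", paste(object$query, collapse = ", "))) +
    ggplot2::theme_minimal()
}

#' Plot the depth profile of an ontology
#'
#' @param object An [assign_depths()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of the number of terms per depth level.
#' @export
autoplot.go_depths <- function(object, ...) {
  df <- as_tibble(object) |>
    dplyr::count(.data$depth, .data$label)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$depth), y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "is-a depth", y = "terms") +
    ggplot2::theme_minimal()
}
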