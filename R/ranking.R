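#' Cumulative hypergeometric term score
#'
#' The score of a term against a microarray reference is the cumulative
#' hypergeometric (one-sided Fisher) mass
#' \deqn{S = \sum_{i=0}^{k-1} \frac{\binom{b}{i}\binom{a-b}{c-i}}{\binom{a}{c}}}
#' where `a` is the number of genes on the array, `b` the number of those
#' annotated to the term, `c` the number of significant genes, and `k` the
#' number of significant genes annotated to the term.  The sum is
#' evaluated in log space (log-gamma binomial coefficients), so array
#' sizes in the tens of thousands do not overflow.  `k = 0` yields 0 (an
#' empty sum); the score reaches 1 once `k - 1 >= min(b, c)`.
#'
#' @param a Number of genes in the microarray universe.
#' @param b Number of universe genes annotated to the term (`b <= a`).
#' @param c Number of significant genes (`c <= a`).
#' @param k Number of significant genes annotated to the term
#'   (`k <= min(b, c)`).
#' @return The score, a probability in `[0, 1]`.
#' @examples
#' cumulative_hypergeom_score(10, 5, 4, 2)  # 55/210
#' @export
cumulative_hypergeom_score <- function(a, b, c, k) {
  for (x in list(a = a, b = b, c = c, k = k)) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 ||
        x != round(x)) {
      abort("`a`, `b`, `c`, `k` must be single non-negative integers.")
    }
  }
  if (b > a) abort("`b` must not exceed `a`.")
  if (c > a) abort("`c` must not exceed `a`.")
  if (k > min(b, c)) abort("`k` must not exceed min(b, c).")
  if (k == 0) return(0)
  i <- 0:(k - 1)
  logterms <- lchoose(b, i) + lchoose(a - b, c - i) - lchoose(a, c)
  s <- sum(exp(logterms))
  min(s, 1)
}

#' Score terms against a microarray reference
#'
#' Computes the [cumulative_hypergeom_score()] of each term, taking `b`
#' and `k` from the annotations restricted to the microarray universe
#' (terms annotating no universe gene score 0).
#'
#' @param microarray A [parse_microarray()] result.
#' @param annotations A [parse_annotations()] result.
#' @param terms Character vector of term identifiers to score.
#' @return A tibble with columns `term`, `a`, `b`, `c`, `k`, `score`.
#' @export
term_score <- function(microarray, annotations, terms) {
  stopifnot(inherits(microarray, "go_microarray"),
            inherits(annotations, "go_annotations"))
  terms <- as.character(terms)
  universe <- microarray$gene
  sig <- microarray$gene[microarray$significant]
  a <- length(universe)
  c <- length(sig)
  rows <- lapply(terms, function(t) {
    genes <- unique(annotations$gene[annotations$term == t])
    genes <- genes[genes %in% universe]
    b <- length(genes)
    k <- sum(genes %in% sig)
    tibble(term = t, a = a, b = b, c = c, k = k,
           score = if (b == 0) 0 else cumulative_hypergeom_score(a, b, c, k))
  })
  bind_rows(rows)
}

#' Rank of a keyword context from its part-of neighbourhood
#'
#' The rank of an annotation term is a PageRank-style combination of its
#' own score and the normalised scores of its neighbours in the part-of
#' graph:
#' \deqn{R(KC) = (1 - p_1 - p_2)\,S(KC)
#'   + p_1 \sum_{v \in parents} S(v)/N_i(v)
#'   + p_2 \sum_{v \in children} S(v)/N_i(v)}
#' where `Ni(v)` is the number of part-of edges entering `v` (its number
#' of children), floored at 1.  With the default `p1 + p2 = 1` the
#' self-score coefficient vanishes.  The first sum runs over the term's
#' POG parents (navigation away from the term), the second over its POG
#' children (navigation back to it); `kcrank_graph = "go"` in `params`
#' takes the neighbourhood from the raw ontology graph instead.
#'
#' @param pog A [build_pog()] result.
#' @param kc A term identifier.
#' @param scores A [term_score()] tibble (or any data frame with `term`
#'   and `score`) covering `kc` and its neighbours; missing terms score 0.
#' @param params A [grank_params()].
#' @param graph The source [go_graph()]; only needed for
#'   `kcrank_graph = "go"`.
#' @return The rank, a non-negative number.
#' @export
kc_rank <- function(pog, kc, scores, params = grank_params(), graph = NULL) {
  stopifnot(inherits(pog, "go_pog"))
  if (!kc %in% pog$terms$term) abort(paste0("Unknown term: ", kc))
  smap <- score_map(scores)

  edges <- if (params$kcrank_graph == "go") {
    if (is.null(graph)) abort("`kcrank_graph = \"go\"` requires `graph`.")
    graph$edges[, c("child", "parent")]
  } else {
    pog$edges[, c("child", "parent")]
  }
  parents <- sort(unique(edges$parent[edges$child == kc]))
  children <- sort(unique(edges$child[edges$parent == kc]))
  indeg <- table(edges$parent)
  ni <- function(v) {
    x <- suppressWarnings(as.integer(indeg[v]))
    max(1L, if (is.na(x)) 0L else x)
  }
  s <- function(v) smap[[v]] %||% 0

  contrib <- function(vs) {
    if (length(vs) == 0) return(0)
    sum(vapply(vs, function(v) s(v) / ni(v), numeric(1)))
  }
  (1 - params$p1 - params$p2) * s(kc) +
    params$p1 * contrib(parents) +
    params$p2 * contrib(children)
}

score_map <- function(scores) {
  if (is.numeric(scores) && !is.null(names(scores))) {
    as.list(scores)
  } else {
    df <- as_tibble(scores)
    setNames(as.list(df$score), df$term)
  }
}

#' Decay-attenuated rank of a candidate with respect to one keyword context
#'
#' Scales a keyword context's rank down by `decay^(j - 1)`, where `j >= 1`
#' is the number of hierarchical levels between the candidate and the
#' keyword context (the absolute is-a depth difference, floored at 1, so
#' adjacent levels leave the rank unchanged).
#'
#' @param r The keyword context's rank, from [kc_rank()].
#' @param j Number of hierarchical levels between candidate and keyword
#'   context (`>= 1`).
#' @param params A [grank_params()] supplying `decay`.
#' @return The attenuated rank.
#' @examples
#' rank_wrt_kc(2, 3, grank_params(decay = 0.7))  # 2 * 0.7^2 = 0.98
#' @export
rank_wrt_kc <- function(r, j, params = grank_params()) {
  if (!is.numeric(j) || length(j) != 1 || j < 1) {
    abort("`j` must be a single integer >= 1.")
  }
  r * params$decay^(j - 1)
}

#' Combine per-term ranks of one gene
#'
#' When a gene is annotated to several terms, the ranks of a candidate
#' with respect to each of them are combined with an aggregation function:
#' the maximum (default) or the sum.
#'
#' @param values Non-empty numeric vector of ranks.
#' @param params A [grank_params()] supplying `aggregation`.
#' @return A single combined rank.
#' @export
combined_rank <- function(values, params = grank_params()) {
  if (length(values) == 0) abort("Cannot combine an empty set of ranks.")
  switch(params$aggregation, max = max(values), sum = sum(values))
}

#' Keyword proximity of a set of annotation terms
#'
#' Proximity is inversely proportional to the smallest window in the
#' ontology drawing that contains all the annotation terms of the query
#' genes.  The window height is the number of hierarchical levels spanned
#' (`max depth - min depth + 1`); its width is the horizontal span under a
#' canonical left-to-right order, taken as the lexicographic term order
#' within each depth layer of the full depth map.  `prox = 1/(height *
#' width)` lies in `(0, 1]` and equals 1 when all genes are annotated to a
#' single term.
#'
#' @param depths An [assign_depths()] result (supplies the layers).
#' @param terms Non-empty character vector of annotation terms.
#' @return A one-row tibble with columns `height`, `width`, `prox`.
#' @export
proximity <- function(depths, terms) {
  stopifnot(inherits(depths, "go_depths"))
  terms <- unique(as.character(terms))
  if (length(terms) == 0) abort("Need at least one term.")
  unknown <- setdiff(terms, depths$term)
  if (length(unknown) > 0) {
    abort(paste0("Unknown term(s): ", paste(unknown, collapse = ", ")))
  }
  layer_pos <- depths |>
    as_tibble() |>
    group_by(.data$depth) |>
    arrange(.data$term, .by_group = TRUE) |>
    mutate(pos = dplyr::row_number()) |>
    ungroup()
  sel <- layer_pos[layer_pos$term %in% terms, ]
  height <- diff(range(sel$depth)) + 1L
  width <- diff(range(sel$pos)) + 1L
  tibble(height = as.integer(height), width = as.integer(width),
         prox = 1 / (height * width))
}

#' Rank the meaningful candidates of a query
#'
#' Scores every meaningful candidate term: for each query gene the
#' candidate's decay-attenuated rank with respect to each of the gene's
#' annotation terms is aggregated ([combined_rank()]); the per-gene values
#' are summed and multiplied by the [proximity()] of all the query's
#' annotation terms.  Result rows carry the genes directly annotated to
#' the candidate (minus the query genes when `exclude_query_genes`).
#'
#' @param verdicts A [meaningful_candidates()] tibble.
#' @param kcs_by_gene A [map_query_to_kcs()] tibble.
#' @param pog A [build_pog()] result.
#' @param depths An [assign_depths()] result.
#' @param scores A [term_score()] tibble covering the keyword contexts and
#'   their POG neighbours.
#' @param annotations A [parse_annotations()] result (for the answer
#'   genes).
#' @param params A [grank_params()].
#' @param graph Source [go_graph()], only for `kcrank_graph = "go"`.
#' @return A tibble of class `grank_ranking` with columns `rank`, `term`,
#'   `role`, `score`, `genes` (list-column), `n_genes`, sorted by
#'   descending score with deterministic lexicographic tie-breaks.  Empty
#'   (with a warning) when no candidate is meaningful.
#' @export
rank_answers <- function(verdicts, kcs_by_gene, pog, depths, scores,
                         annotations, params = grank_params(), graph = NULL) {
  stopifnot(inherits(pog, "go_pog"), inherits(depths, "go_depths"))
  meaningful <- verdicts[verdicts$meaningful, , drop = FALSE]
  if (nrow(meaningful) == 0) {
    warn("No meaningful candidate term; returning an empty ranking.")
    return(empty_ranking())
  }
  dmap <- setNames(depths$depth, depths$term)
  query_genes <- unique(kcs_by_gene$gene)
  per_gene <- lapply(split(kcs_by_gene$term, kcs_by_gene$gene),
                     function(x) sort(unique(x)))
  kc_ranks <- setNames(
    lapply(sort(unique(kcs_by_gene$term)), function(kc) {
      kc_rank(pog, kc, scores, params, graph)
    }),
    sort(unique(kcs_by_gene$term))
  )
  prox <- proximity(depths, kcs_by_gene$term)$prox

  rows <- lapply(seq_len(nrow(meaningful)), function(i) {
    cand <- meaningful$candidate[[i]]
    role <- meaningful$role[[i]]
    total <- sum(vapply(per_gene, function(kcs) {
      vals <- vapply(kcs, function(kc) {
        j <- max(1L, abs(dmap[[cand]] - dmap[[kc]]))
        rank_wrt_kc(kc_ranks[[kc]], j, params)
      }, numeric(1))
      combined_rank(vals, params)
    }, numeric(1)))
    genes <- sort(unique(annotations$gene[annotations$term == cand]))
    if (params$exclude_query_genes) genes <- setdiff(genes, query_genes)
    n_genes <- length(genes)
    tibble(term = cand, role = role, score = total * prox,
           genes = list(genes), n_genes = n_genes)
  })

  out <- bind_rows(rows) |>
    arrange(dplyr::desc(.data$score), .data$term, .data$role) |>
    mutate(rank = dplyr::row_number()) |>
    select("rank", "term", "role", "score", "genes", "n_genes")
  structure(out, prox = prox, class = c("grank_ranking", class(out)))
}

empty_ranking <- function() {
  out <- tibble(rank = integer(), term = character(), role = character(),
                score = numeric(), genes = list(), n_genes = integer())
  structure(out, prox = NA_real_, class = c("grank_ranking", class(out)))
}
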