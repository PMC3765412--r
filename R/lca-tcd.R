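#' Lowest common ancestors / top common descendants in the POG
#'
#' `lowest_common_ancestors()` returns every part-of-graph ancestor common
#' to all the given terms (a term that is an ancestor of the others counts
#' as its own ancestor) that has no POG descendant which is also a common
#' ancestor.  `top_common_descendants()` is the mirror image with the edge
#' direction reversed.  Both return the empty set when no common
#' ancestor/descendant exists.
#'
#' @param pog A [build_pog()] result.
#' @param terms Character vector of term identifiers (at least one).
#' @return Character vector of term identifiers, lexicographically sorted.
#' @export
lowest_common_ancestors <- function(pog, terms) {
  common_extrema(pog, terms, up = TRUE)
}

#' @rdname lowest_common_ancestors
#' @export
top_common_descendants <- function(pog, terms) {
  common_extrema(pog, terms, up = FALSE)
}

common_extrema <- function(pog, terms, up) {
  stopifnot(inherits(pog, "go_pog"))
  terms <- unique(as.character(terms))
  if (length(terms) < 1) abort("Need at least one term.")
  unknown <- setdiff(terms, pog$terms$term)
  if (length(unknown) > 0) {
    abort(paste0("Unknown term(s): ", paste(unknown, collapse = ", ")))
  }
  closures <- lapply(terms, function(t) c(t, pog_reach(pog, t, up = up)))
  common <- Reduce(intersect, closures)
  if (length(common) == 0) return(character())
  # keep only the extremal members: no strictly closer common node below
  # (ancestor case) / above (descendant case)
  keep <- vapply(common, function(a) {
    below <- pog_reach(pog, a, up = !up)
    !any(below %in% common)
  }, logical(1))
  sort(common[keep])
}

#' Decide whether a candidate LCA/TCD is meaningful
#'
#' A candidate common ancestor (role `"lca"`) or common descendant (role
#' `"tcd"`) of a set of keyword contexts is *meaningful* when (1) its is-a
#' depth differs from the depth of every keyword context, and (2) the POG
#' path between the candidate and each keyword context contains no two
#' terms of equal depth (endpoints included).  Under the default
#' `semantics = "all"` every directed POG path between the pair must be
#' depth-distinct; `semantics = "exists"` accepts the candidate when at
#' least one clean path exists.  A keyword context equal to the candidate
#' itself is trivially satisfied, so a single term is its own meaningful
#' LCA and TCD.
#'
#' @param pog A [build_pog()] result.
#' @param depths An [assign_depths()] result for the source graph.
#' @param kcs Character vector: the keyword contexts (annotation terms).
#' @param candidate A term that is a common ancestor (lca) or common
#'   descendant (tcd) of `kcs`; anything else is an error.
#' @param role `"lca"` or `"tcd"`.
#' @param semantics `"all"` (default) or `"exists"`; see Details.
#' @return A list of class `grank_verdict` with elements `candidate`,
#'   `role`, `meaningful`, and (on failure) `witness`: either a depth
#'   equality between candidate and a keyword context, or an offending
#'   path with its first equal-depth pair.  Keyword contexts and paths are
#'   examined in lexicographic order, so the witness is deterministic.
#' @examples
#' ex <- nephrogenesis_example()
#' pog <- build_pog(ex$graph)
#' d <- assign_depths(ex$graph)
#' is_meaningful(pog, d, c("GO:0072006", "GO:0072009"), "GO:0048513", "lca")
#' @export
is_meaningful <- function(pog, depths, kcs, candidate,
                          role = c("lca", "tcd"),
                          semantics = c("all", "exists")) {
  role <- match.arg(role)
  semantics <- match.arg(semantics)
  stopifnot(inherits(pog, "go_pog"), inherits(depths, "go_depths"))
  kcs <- sort(unique(as.character(kcs)))
  up <- role == "lca"   # candidate sits above (lca) or below (tcd) the kcs

  dmap <- setNames(depths$depth, depths$term)
  if (is.na(dmap[candidate])) abort(paste0("Unknown candidate: ", candidate))

  # adjacency towards the candidate: upward for LCAs, downward for TCDs
  edges <- pog$edges
  adj <- if (up) split(edges$parent, edges$child) else split(edges$child, edges$parent)
  adj <- lapply(adj, sort)

  verdict <- function(meaningful, witness = NULL) {
    structure(list(candidate = candidate, role = role,
                   meaningful = meaningful, witness = witness),
              class = "grank_verdict")
  }

  for (kc in kcs) {
    if (is.na(dmap[kc])) abort(paste0("Unknown keyword context: ", kc))
    if (kc == candidate) next
    reach <- pog_reach(pog, kc, up = up)
    if (!candidate %in% reach) {
      abort(sprintf("Candidate %s is not a common %s of the keyword contexts.",
                    candidate, if (up) "ancestor" else "descendant"))
    }
    if (dmap[[candidate]] == dmap[[kc]]) {
      return(verdict(FALSE, list(type = "depth_equality", kc = kc,
                                 candidate = candidate,
                                 depth = dmap[[kc]])))
    }
    # restrict the walk to terms lying between kc and candidate, so only
    # genuine kc-candidate paths are examined
    interval <- intersect(c(kc, reach),
                          c(candidate, pog_reach(pog, candidate, up = !up)))
    adj_int <- lapply(adj, function(x) x[x %in% interval])
    bad <- check_paths(adj_int, dmap, from = kc, to = candidate, semantics)
    if (!is.null(bad)) {
      return(verdict(FALSE, c(list(type = "path", kc = kc), bad)))
    }
  }
  verdict(TRUE)
}

# Depth-first enumeration of all directed paths from `from` to `to`,
# neighbours in lexicographic order.  Returns NULL when the semantics are
# satisfied, otherwise the first offending path and its equal-depth pair.
check_paths <- function(adj, dmap, from, to, semantics) {
  first_bad <- NULL
  any_clean <- FALSE
  walk <- function(node, path, depths_seen) {
    if (!is.null(first_bad) && semantics == "all") return()
    dup <- dmap[[node]] %in% depths_seen
    path <- c(path, node)
    depths_seen <- c(depths_seen, dmap[[node]])
    if (dup && is.null(first_bad)) {
      pair <- path[dmap[path] == dmap[[node]]]
      first_bad <<- list(path = path, pair = pair[1:2],
                         depth = dmap[[node]])
      # a dirty prefix taints every completion; no need to extend it
      return()
    }
    if (node == to) {
      if (!dup) any_clean <<- TRUE
      return()
    }
    for (nb in adj[[node]] %||% character()) {
      walk(nb, path, depths_seen)
    }
  }
  walk(from, character(), integer())
  if (semantics == "all") {
    first_bad
  } else {
    if (any_clean) NULL else first_bad %||%
      list(path = character(), pair = character(), depth = NA_integer_)
  }
}

#' @export
print.grank_verdict <- function(x, ...) {
  cat(sprintf("<grank_verdict> %s as %s: %s\n", x$candidate, toupper(x$role),
              if (x$meaningful) "meaningful" else "meaningless"))
  if (!is.null(x$witness)) {
    w <- x$witness
    if (w$type == "depth_equality") {
      cat(sprintf("  witness: candidate depth equals depth of %s (%d)\n",
                  w$kc, w$depth))
    } else {
      cat(sprintf("  witness: path %s contains equal-depth pair %s (depth %d)\n",
                  paste(w$path, collapse = " -> "),
                  paste(w$pair, collapse = ", "), w$depth))
    }
  }
  invisible(x)
}

#' Enumerate candidate terms for a query and attach verdicts
#'
#' For every combination that selects one keyword context per query gene,
#' enumerates the lowest common ancestors and top common descendants of
#' the selected set and screens each with [is_meaningful()].  Candidates
#' are deduplicated by (term, role); a candidate is meaningful if it is
#' meaningful under at least one combination.
#'
#' @param pog A [build_pog()] result.
#' @param depths An [assign_depths()] result.
#' @param kcs_by_gene A tibble with columns `gene`, `term` as returned by
#'   [map_query_to_kcs()].
#' @param semantics Path semantics passed to [is_meaningful()].
#' @return A tibble with columns `candidate`, `role`, `meaningful` and a
#'   `witness` list-column (`NULL` for meaningful candidates).
#' @export
meaningful_candidates <- function(pog, depths, kcs_by_gene,
                                  semantics = c("all", "exists")) {
  semantics <- match.arg(semantics)
  stopifnot(inherits(pog, "go_pog"), inherits(depths, "go_depths"))
  kcs_by_gene <- as_tibble(kcs_by_gene)
  if (nrow(kcs_by_gene) == 0) abort("Need at least one gene with a keyword context.")

  per_gene <- lapply(split(kcs_by_gene$term, kcs_by_gene$gene),
                     function(x) sort(unique(x)))
  per_gene <- per_gene[unique(kcs_by_gene$gene)]  # keep query order
  combos <- expand.grid(per_gene, stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)

  rows <- list()
  seen <- character()
  for (i in seq_len(nrow(combos))) {
    kcset <- sort(unique(unlist(combos[i, ], use.names = FALSE)))
    for (role in c("lca", "tcd")) {
      cands <- if (role == "lca") {
        lowest_common_ancestors(pog, kcset)
      } else {
        top_common_descendants(pog, kcset)
      }
      for (cand in cands) {
        v <- is_meaningful(pog, depths, kcset, cand, role, semantics)
        key <- paste(cand, role)
        prev <- match(key, seen)
        if (is.na(prev)) {
          seen <- c(seen, key)
          rows[[length(rows) + 1L]] <- list(
            candidate = cand, role = role,
            meaningful = v$meaningful, witness = v$witness
          )
        } else if (v$meaningful && !rows[[prev]]$meaningful) {
          rows[[prev]]$meaningful <- TRUE
          rows[[prev]]$witness <- NULL
        }
      }
    }
  }

  if (length(rows) == 0) {
    return(tibble(candidate = character(), role = character(),
                  meaningful = logical(), witness = list()))
  }
  tibble(
    candidate = vapply(rows, `[[`, character(1), "candidate"),
    role = vapply(rows, `[[`, character(1), "role"),
    meaningful = vapply(rows, `[[`, logical(1), "meaningful"),
    witness = lapply(rows, `[[`, "witness")
  ) |>
    arrange(.data$candidate, .data$role)
}
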