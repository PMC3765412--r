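#' Assign is-a depths to all terms
#'
#' The depth of a term is the number of is-a relations connecting it to its
#' namespace root; under multiple inheritance the *longest* is-a distance
#' is taken.  Part-of edges never contribute to depth.  Terms with no is-a
#' route to a root (reachable only via part-of) receive depth 0 and are
#' flagged `unrooted` with a warning.  Implemented as a longest-path sweep
#' over a topological order of the is-a subgraph, which is linear on a DAG.
#'
#' @param graph A [go_graph()].
#' @return A tibble of class `go_depths` with columns `term`, `depth`,
#'   `label` (alphabetical rendering of the level, see [depth_label()]) and
#'   `unrooted`.
#' @examples
#' g <- go_graph(
#'   data.frame(term = c("A", "B", "C", "D")),
#'   data.frame(child = c("B", "C", "D", "D"),
#'              parent = c("A", "B", "B", "C"),
#'              relation = "is_a")
#' )
#' assign_depths(g)  # D sits at depth 3 via A-B-C-D, not 2 via A-B-D
#' @export
assign_depths <- function(graph) {
  stopifnot(inherits(graph, "go_graph"))
  terms <- graph$terms$term
  isa <- graph$edges[graph$edges$relation == "is_a", , drop = FALSE]

  depth <- setNames(integer(length(terms)), terms)
  rooted <- setNames(terms %in% graph$roots$term, terms)

  if (nrow(isa) > 0) {
    ig <- igraph::graph_from_data_frame(isa[, c("child", "parent")],
                                        directed = TRUE, vertices = terms)
    # topo order of child->parent edges lists children before parents;
    # reverse it so every parent is finalised before its children.
    ord <- rev(names(igraph::topo_sort(ig, mode = "out")))
    parents_of <- split(isa$parent, isa$child)
    for (v in ord) {
      ps <- parents_of[[v]]
      if (!is.null(ps)) {
        depth[[v]] <- max(depth[ps]) + 1L
        rooted[[v]] <- any(rooted[ps])
      }
    }
  }

  # a term whose is-a chain tops out at a non-root (part-of-only attachment)
  unrooted <- setNames(!rooted, terms)
  if (any(unrooted)) {
    warn(paste0("Term(s) with no is-a path to a root (depth set to their ",
                "local is-a depth): ",
                paste(head(names(which(unrooted)), 5), collapse = ", ")))
  }

  out <- tibble(
    term = terms,
    depth = as.integer(depth),
    label = depth_label(as.integer(depth)),
    unrooted = unname(unrooted)
  )
  structure(out, class = c("go_depths", class(out)))
}

#' Alphabetical label of a hierarchical level
#'
#' Renders a depth as a spreadsheet-style letter: 0 is "A", 25 is "Z",
#' 26 is "AA", 27 is "AB", and so on (bijective base-26).
#'
#' @param d Vector of non-negative integers.
#' @return A character vector of labels.
#' @examples
#' depth_label(c(0, 2, 25, 26, 27))
#' @export
depth_label <- function(d) {
  d <- as.integer(d)
  if (any(is.na(d)) || any(d < 0)) abort("Depths must be non-negative integers.")
  vapply(d, function(n) {
    n <- n + 1L   # bijective numbering is 1-based
    label <- character()
    while (n > 0L) {
      r <- (n - 1L) %% 26L
      label <- c(LETTERS[r + 1L], label)
      n <- (n - 1L) %/% 26L
    }
    paste(label, collapse = "")
  }, character(1))
}

#' Export a depth map as TSV
#'
#' @param depths An [assign_depths()] result.
#' @param file Optional path; if omitted the lines are returned invisibly.
#' @return The TSV lines (`term`, `depth`, `label`), invisibly.
#' @export
write_depths <- function(depths, file = NULL) {
  stopifnot(inherits(depths, "go_depths"))
  lines <- c("term\tdepth\tlabel",
             sprintf("%s\t%d\t%s", depths$term, depths$depth, depths$label))
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
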