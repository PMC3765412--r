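#' Construct an ontology graph
#'
#' An ontology graph holds terms and the typed, directed edges between them.
#' Edges point from the child (more specific term) to the parent and carry a
#' relation type, `"is_a"` or `"part_of"`.  The graph must be acyclic over
#' the union of both relation types; roots are terms with no parent of
#' either type.
#'
#' @param terms A data frame with columns `term`, and optionally `name` and
#'   `namespace` (missing columns are filled with the term id and
#'   `"default"`).
#' @param edges A data frame with columns `child`, `parent`, `relation`
#'   (values `"is_a"` / `"part_of"`).  May have zero rows.
#'
#' @return A list of class `go_graph` with tibbles `terms`,
#'   `edges` and `roots`.
#' @examples
#' g <- go_graph(
#'   terms = data.frame(term = c("A", "B", "C")),
#'   edges = data.frame(child = c("B", "C"), parent = c("A", "B"),
#'                      relation = c("is_a", "part_of"))
#' )
#' g
#' @export
go_graph <- function(terms, edges = NULL) {
  terms <- as_tibble(terms)
  if (!"term" %in% names(terms)) abort("`terms` needs a `term` column.")
  if (any(is.na(terms$term)) || any(terms$term == "")) {
    abort("Term identifiers must be non-empty.")
  }
  if (anyDuplicated(terms$term)) {
    abort("Term identifiers must be unique within a graph.")
  }
  if (!"name" %in% names(terms)) terms$name <- terms$term
  if (!"namespace" %in% names(terms)) terms$namespace <- "default"
  terms <- terms[, c("term", "name", "namespace")]

  if (is.null(edges) || nrow(as_tibble(edges)) == 0) {
    edges <- tibble(child = character(), parent = character(),
                    relation = character())
  } else {
    edges <- as_tibble(edges)[, c("child", "parent", "relation")]
    edges <- distinct(edges)
  }
  validate_go_edges(terms, edges)

  has_parent <- unique(edges$child)
  roots <- terms |>
    filter(!.data$term %in% has_parent) |>
    select("term", "namespace")

  structure(
    list(terms = terms, edges = edges, roots = roots),
    class = "go_graph"
  )
}

validate_go_edges <- function(terms, edges) {
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel) > 0) {
    abort(paste0("Unknown relation type(s): ", paste(bad_rel, collapse = ", ")))
  }
  unknown <- setdiff(c(edges$child, edges$parent), terms$term)
  if (length(unknown) > 0) {
    abort(paste0("Edge endpoint(s) not in term set: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (any(edges$child == edges$parent)) {
    abort("Self-edges are not allowed.")
  }
  if (nrow(edges) > 0) {
    ig <- igraph::graph_from_data_frame(
      edges[, c("child", "parent")], directed = TRUE,
      vertices = terms$term
    )
    if (!igraph::is_dag(ig)) {
      cyc <- find_one_cycle(edges)
      abort(paste0("Ontology graph contains a cycle: ",
                   paste(cyc, collapse = " -> ")))
    }
  }
  invisible(TRUE)
}

# Locate one directed cycle for the error message (graph is small by then).
find_one_cycle <- function(edges) {
  adj <- split(edges$parent, edges$child)
  state <- new.env(parent = emptyenv())
  path <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    st <- get0(v, envir = state, ifnotfound = "white")
    if (st == "gray") {
      i <- match(v, path)
      found <<- c(path[i:length(path)], v)
      return()
    }
    if (st == "black") return()
    assign(v, "gray", envir = state)
    path <<- c(path, v)
    for (p in adj[[v]] %||% character()) visit(p)
    path <<- path[-length(path)]
    assign(v, "black", envir = state)
  }
  for (v in unique(edges$child)) visit(v)
  found %||% "(cycle not reconstructed)"
}

#' @export
print.go_graph <- function(x, ...) {
  cat(sprintf("<go_graph> %d terms, %d edges (%d is_a, %d part_of), %d root(s)\n",
              nrow(x$terms), nrow(x$edges),
              sum(x$edges$relation == "is_a"),
              sum(x$edges$relation == "part_of"),
              nrow(x$roots)))
  invisible(x)
}

#' Terms and edges of an ontology graph
#'
#' Accessors returning the tibbles backing a [go_graph()].
#'
#' @param graph A `go_graph`.
#' @return A tibble of terms (`go_terms()`) or edges (`go_edges()`).
#' @export
go_terms <- function(graph) {
  stopifnot(inherits(graph, "go_graph"))
  graph$terms
}

#' @rdname go_terms
#' @export
go_edges <- function(graph) {
  stopifnot(inherits(graph, "go_graph"))
  graph$edges
}

#' Read an ontology from OBO text
#'
#' Parses the `[Term]` stanzas of an OBO 1.2 file into a [go_graph()].
#' Recognised tags are `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`, and `is_obsolete`; obsolete stanzas are skipped
#' and relationship types other than `part_of` are ignored with one summary
#' warning.  Acyclicity is verified after parsing.
#'
#' @param file Path to an OBO file, or a character vector of OBO lines.
#' @return A `go_graph`.
#' @examples
#' obo <- c("[Term]", "id: GO:1", "name: root", "",
#'          "[Term]", "id: GO:2", "name: leaf", "is_a: GO:1 ! root")
#' parse_obo(obo)
#' @export
parse_obo <- function(file) {
  lines <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else if (length(file) == 1 && grepl("\n", file)) {
    strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(file)
  }

  default_ns <- "default"
  header <- grep("^default-namespace:", lines, value = TRUE)
  if (length(header) > 0) {
    default_ns <- trimws(sub("^default-namespace:", "", header[[1]]))
  }

  stanza_starts <- which(trimws(lines) == "[Term]")
  other_starts <- which(grepl("^\\[", trimws(lines)) & trimws(lines) != "[Term]")
  boundaries <- sort(c(stanza_starts, other_starts, length(lines) + 1L))

  terms <- list()
  edges <- list()
  skipped_rel <- character()

  for (s in stanza_starts) {
    end <- min(boundaries[boundaries > s]) - 1L
    body_idx <- seq(s + 1L, length.out = max(0L, end - s))
    id <- NULL; nm <- NULL; ns <- default_ns; obsolete <- FALSE
    isa <- character(); partof <- character()
    for (i in body_idx) {
      line <- sub("\\s*!.*$", "", lines[[i]])  # strip trailing OBO comments
      line <- trimws(line)
      if (line == "") next
      if (!grepl("^[A-Za-z_]+\\s*:", line)) {
        abort(sprintf("Malformed OBO line %d: \"%s\"", i, trimws(lines[[i]])))
      }
      tag <- sub("^([A-Za-z_]+)\\s*:.*$", "\\1", line)
      val <- trimws(sub("^[A-Za-z_]+\\s*:", "", line))
      if (tag == "id") id <- val
      else if (tag == "name") nm <- val
      else if (tag == "namespace") ns <- val
      else if (tag == "is_obsolete") obsolete <- identical(tolower(val), "true")
      else if (tag == "is_a") isa <- c(isa, sub("\\s.*$", "", val))
      else if (tag == "relationship") {
        parts <- strsplit(val, "\\s+")[[1]]
        if (length(parts) < 2) {
          abort(sprintf("Malformed relationship at OBO line %d", i))
        }
        if (parts[[1]] == "part_of") partof <- c(partof, parts[[2]])
        else skipped_rel <- c(skipped_rel, parts[[1]])
      }
      # other tags (def, synonym, ...) are ignored
    }
    if (is.null(id)) {
      abort(sprintf("OBO [Term] stanza starting at line %d has no id", s))
    }
    if (obsolete) next
    terms[[length(terms) + 1L]] <- tibble(
      term = id, name = nm %||% id, namespace = ns
    )
    if (length(isa) > 0) {
      edges[[length(edges) + 1L]] <- tibble(child = id, parent = isa,
                                            relation = "is_a")
    }
    if (length(partof) > 0) {
      edges[[length(edges) + 1L]] <- tibble(child = id, parent = partof,
                                            relation = "part_of")
    }
  }

  if (length(skipped_rel) > 0) {
    warn(paste0("Ignored relationship type(s): ",
                paste(sort(unique(skipped_rel)), collapse = ", ")))
  }
  if (length(terms) == 0) abort("No [Term] stanzas found in OBO input.")
  go_graph(bind_rows(terms), if (length(edges) > 0) bind_rows(edges))
}

#' Write an ontology graph as OBO text
#'
#' Serialises a [go_graph()] to the OBO 1.2 stanza subset read by
#' [parse_obo()], so that `parse_obo(write_obo(g))` reproduces `g`.
#'
#' @param graph A `go_graph`.
#' @param file Optional path; if omitted the OBO lines are returned
#'   invisibly as a character vector.
#' @return The OBO lines, invisibly.
#' @export
write_obo <- function(graph, file = NULL) {
  stopifnot(inherits(graph, "go_graph"))
  out <- c("format-version: 1.2", "")
  by_child <- split(graph$edges, graph$edges$child)
  for (i in seq_len(nrow(graph$terms))) {
    t <- graph$terms[i, ]
    stanza <- c("[Term]",
                paste0("id: ", t$term),
                paste0("name: ", t$name),
                paste0("namespace: ", t$namespace))
    e <- by_child[[t$term]]
    if (!is.null(e)) {
      e <- arrange(e, .data$relation, .data$parent)
      stanza <- c(
        stanza,
        paste0("is_a: ", e$parent[e$relation == "is_a"], recycle0 = TRUE),
        paste0("relationship: part_of ", e$parent[e$relation == "part_of"],
               recycle0 = TRUE)
      )
    }
    out <- c(out, stanza, "")
  }
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}
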