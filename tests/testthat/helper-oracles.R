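# Independent brute-force oracles used to validate the graph algorithms.
# They are deliberately naive (repeat-until-stable rule application,
# exhaustive path enumeration) and share no code with the implementation.

# Exhaustive part-of inference: apply the two mixed rules (and optionally
# plain part-of transitivity) until no new pair appears.
oracle_pog_edges <- function(graph, transitive = TRUE) {
  isa <- graph$edges[graph$edges$relation == "is_a", c("child", "parent")]
  po <- graph$edges[graph$edges$relation == "part_of", c("child", "parent")]
  P <- unique(paste(po$child, po$parent))
  I <- paste(isa$child, isa$parent)
  split_pair <- function(p) do.call(rbind, strsplit(p, " ", fixed = TRUE))
  repeat {
    new <- character()
    if (length(P) > 0) {
      pm <- split_pair(P)
      im <- if (length(I) > 0) split_pair(I) else matrix(character(), ncol = 2)
      # rule 1: a is-a b, b part-of c  =>  a part-of c
      for (r in seq_len(nrow(im))) {
        hits <- pm[pm[, 1] == im[r, 2], 2]
        if (length(hits) > 0) new <- c(new, paste(im[r, 1], hits))
      }
      # rule 2: a part-of b, b is-a c  =>  a part-of c
      for (r in seq_len(nrow(pm))) {
        hits <- im[im[, 1] == pm[r, 2], 2, drop = TRUE]
        if (length(hits) > 0) new <- c(new, paste(pm[r, 1], hits))
      }
      if (transitive) {
        for (r in seq_len(nrow(pm))) {
          hits <- pm[pm[, 1] == pm[r, 2], 2]
          if (length(hits) > 0) new <- c(new, paste(pm[r, 1], hits))
        }
      }
    }
    new <- setdiff(unique(new), P)
    if (length(new) == 0) break
    P <- c(P, new)
  }
  sort(P)
}

# Depth by exhaustive enumeration of every upward is-a path.
oracle_depth <- function(graph, term) {
  isa <- graph$edges[graph$edges$relation == "is_a", c("child", "parent")]
  parents_of <- split(isa$parent, isa$child)
  longest <- function(t) {
    ps <- parents_of[[t]]
    if (is.null(ps) || length(ps) == 0) return(0L)
    1L + max(vapply(ps, longest, integer(1)))
  }
  longest(term)
}

# Meaningfulness by exhaustive path enumeration with igraph (independent
# traversal machinery from the package's hand-rolled DFS).
oracle_meaningful <- function(pog, depths, kcs, candidate, role) {
  dmap <- stats::setNames(depths$depth, depths$term)
  ig <- igraph::graph_from_data_frame(pog$edges[, c("child", "parent")],
                                      directed = TRUE,
                                      vertices = pog$terms$term)
  mode <- if (role == "lca") "out" else "in"
  for (kc in kcs) {
    if (kc == candidate) next
    if (dmap[[candidate]] == dmap[[kc]]) return(FALSE)
    paths <- igraph::all_simple_paths(ig, from = kc, to = candidate,
                                      mode = mode)
    for (p in paths) {
      if (anyDuplicated(dmap[names(p)]) > 0) return(FALSE)
    }
  }
  TRUE
}

# Random typed DAG over an index order (edges always point to lower index,
# hence acyclic); independent of the package simulator.
random_typed_dag <- function(n, p_edge = 0.3, p_partof = 0.4) {
  ids <- sprintf("N%02d", seq_len(n))
  rows <- list()
  for (j in 2:n) {
    for (i in 1:(j - 1)) {
      if (stats::runif(1) < p_edge) {
        rel <- if (stats::runif(1) < p_partof) "part_of" else "is_a"
        rows[[length(rows) + 1L]] <- data.frame(child = ids[[j]],
                                                parent = ids[[i]],
                                                relation = rel)
      }
    }
  }
  edges <- if (length(rows) > 0) do.call(rbind, rows) else NULL
  go_graph(data.frame(term = ids), edges)
}

pog_edge_keys <- function(pog) {
  sort(paste(pog$edges$child, pog$edges$parent))
}

quiet_depths <- function(graph) suppressWarnings(assign_depths(graph))
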