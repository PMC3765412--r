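#' A hand-curated nephrogenesis ontology fragment with annotations
#'
#' Builds a small, fully deterministic 29-term fragment of the
#' biological-process ontology centred on kidney and nephron development,
#' together with gene annotations and a small synthetic microarray
#' reference.  It is the package's worked example: it exhibits inferred
#' part-of relations (e.g. system development is part of biological
#' process via two is-a steps), equal-depth term layers, and both
#' meaningful and meaningless common ancestors/descendants, so every stage
#' of the search pipeline can be demonstrated on it.  The exact edge list
#' is a minimal curated completion around the documented facts; the fact
#' suite ([check_example_facts()]) rather than the completion is the
#' contract.
#'
#' Annotated genes: JAG1 (animal organ morphogenesis, nephron epithelium
#' development), LHX1 (nephron development, renal vesicle morphogenesis),
#' Gga.4082 (nephron epithelium morphogenesis), Ssc.22980 (metanephric
#' renal vesicle morphogenesis), Ci-FoxI-c / FKH-4 / fkh-5 (animal organ
#' development), TFAP2B / PANDA_003456 (nephron epithelium development).
#'
#' @return A list of class `grank_example` with elements `graph`
#'   ([go_graph()]), `annotations`, `microarray`.
#' @examples
#' ex <- nephrogenesis_example()
#' ex$graph
#' @export
nephrogenesis_example <- function() {
  terms <- tibble(
    term = c(
      "GO:0008150", "GO:0032501", "GO:0032502", "GO:0007275", "GO:0048731",
      "GO:0001822", "GO:0009653", "GO:0048856", "GO:0048513", "GO:0009887",
      "GO:0035295", "GO:0060429", "GO:0009888", "GO:0001655", "GO:0001656",
      "GO:0001823", "GO:0061440", "GO:0072006", "GO:0072009", "GO:0072077",
      "GO:0060993", "GO:0072001", "GO:0001657", "GO:0072073", "GO:0072088",
      "GO:0072273", "GO:0072028", "GO:0072210", "GO:0072283"
    ),
    name = c(
      "biological_process", "multicellular organismal process",
      "developmental process", "multicellular organism development",
      "system development", "kidney development",
      "anatomical structure morphogenesis", "anatomical structure development",
      "animal organ development", "animal organ morphogenesis",
      "tube development", "epithelium development", "tissue development",
      "urogenital system development", "metanephros development",
      "mesonephros development", "kidney vasculature development",
      "nephron development", "nephron epithelium development",
      "renal vesicle morphogenesis", "kidney morphogenesis",
      "renal system development", "ureteric bud development",
      "kidney epithelium development", "nephron epithelium morphogenesis",
      "metanephric nephron morphogenesis", "nephron morphogenesis",
      "metanephric nephron development",
      "metanephric renal vesicle morphogenesis"
    ),
    namespace = "biological_process"
  )

  isa <- function(child, parent) tibble(child = child, parent = parent,
                                        relation = "is_a")
  po <- function(child, parent) tibble(child = child, parent = parent,
                                       relation = "part_of")
  edges <- bind_rows(
    isa("GO:0032501", "GO:0008150"),
    isa("GO:0032502", "GO:0008150"),
    isa("GO:0007275", "GO:0032501"),
    isa("GO:0048731", "GO:0032502"),
    isa("GO:0001822", "GO:0032502"),
    isa("GO:0009653", "GO:0032502"),
    isa("GO:0048856", "GO:0032502"),
    isa("GO:0048513", "GO:0048856"),
    isa("GO:0009887", "GO:0009653"),
    isa("GO:0035295", "GO:0048856"),
    isa("GO:0060429", "GO:0048856"),
    isa("GO:0009888", "GO:0048856"),
    isa("GO:0001655", "GO:0048731"),
    isa("GO:0001656", "GO:0001822"),
    isa("GO:0001823", "GO:0001822"),
    isa("GO:0061440", "GO:0001822"),
    isa("GO:0072006", "GO:0035295"),
    isa("GO:0072009", "GO:0060429"),
    isa("GO:0072077", "GO:0060429"),
    isa("GO:0060993", "GO:0009887"),
    isa("GO:0072001", "GO:0001655"),
    isa("GO:0001657", "GO:0035295"),
    isa("GO:0072073", "GO:0072001"),
    isa("GO:0072088", "GO:0072009"),
    isa("GO:0072273", "GO:0060993"),
    isa("GO:0072028", "GO:0060993"),
    isa("GO:0072210", "GO:0072006"),
    isa("GO:0072283", "GO:0072077"),
    isa("GO:0072283", "GO:0072273"),
    po("GO:0048731", "GO:0007275"),
    po("GO:0072006", "GO:0048513"),
    po("GO:0072009", "GO:0048513"),
    po("GO:0072073", "GO:0048513"),
    po("GO:0072077", "GO:0072009"),
    po("GO:0072088", "GO:0072009"),
    po("GO:0072088", "GO:0072073"),
    po("GO:0072283", "GO:0072077"),
    po("GO:0072283", "GO:0072088"),
    po("GO:0072283", "GO:0072006")
  )
  graph <- go_graph(terms, edges)

  annotations <- as_go_annotations(tibble(
    gene = c("JAG1", "JAG1", "LHX1", "LHX1", "Gga.4082", "Ssc.22980",
             "Ci-FoxI-c", "FKH-4", "fkh-5", "TFAP2B", "PANDA_003456"),
    term = c("GO:0009887", "GO:0072009", "GO:0072006", "GO:0072077",
             "GO:0072088", "GO:0072283", "GO:0048513", "GO:0048513",
             "GO:0048513", "GO:0072009", "GO:0072009")
  ), graph)

  universe <- c(unique(annotations$gene), sprintf("REF%03d", 1:41))
  significant <- c("Ci-FoxI-c", "FKH-4", "fkh-5", "Ssc.22980", "TFAP2B",
                   sprintf("REF%03d", seq(7, 41, by = 7)))
  microarray <- as_go_microarray(universe, significant)

  structure(
    list(graph = graph, annotations = annotations, microarray = microarray),
    class = "grank_example"
  )
}

#' Verify the documented facts of the bundled example
#'
#' Asserts every documented property of [nephrogenesis_example()]: the
#' inferred part-of relation from system development to the root; the
#' equal-depth layers; the part-of reachability between the nephron
#' terms; and the meaningful/meaningless verdicts of the worked queries.
#' Violated facts are collected and reported together.
#'
#' @param example A [nephrogenesis_example()] bundle (built afresh when
#'   omitted).
#' @return `TRUE` invisibly; errors with the list of violated facts
#'   otherwise.
#' @export
check_example_facts <- function(example = nephrogenesis_example()) {
  g <- example$graph
  pog <- build_pog(g)
  d <- assign_depths(g)
  dmap <- setNames(d$depth, d$term)
  failures <- character()
  fact <- function(ok, what) {
    if (!isTRUE(ok)) failures <<- c(failures, what)
  }

  fact(nrow(g$terms) == 29, "graph has 29 terms")
  pe <- paste(pog$edges$child, pog$edges$parent)
  fact("GO:0048731 GO:0008150" %in% pe,
       "inferred: system development part-of biological process")

  same_depth <- function(ts) length(unique(dmap[ts])) == 1
  fact(same_depth(c("GO:0032501", "GO:0032502")),
       "depth layer: organismal/developmental process")
  fact(same_depth(c("GO:0001822", "GO:0048731", "GO:0007275", "GO:0009653")),
       "depth layer: kidney/system/organism development, morphogenesis")
  fact(same_depth(c("GO:0072009", "GO:0072077")),
       "depth layer: nephron epithelium dev / renal vesicle morph")
  fact(same_depth(c("GO:0072073", "GO:0072088")),
       "depth layer: kidney epithelium dev / nephron epithelium morph")

  fact("GO:0072009" %in% pog_ancestors(pog, "GO:0072077"),
       "nephron epithelium development above renal vesicle morphogenesis")
  fact("GO:0072009" %in% pog_ancestors(pog, "GO:0072088"),
       "nephron epithelium development above nephron epithelium morphogenesis")
  anc88 <- pog_ancestors(pog, "GO:0072088")
  fact(all(c("GO:0048513", "GO:0072073") %in% anc88),
       "organ development above nephron epithelium morphogenesis via kidney epithelium development")
  fact("GO:0048513" %in% pog_ancestors(pog, "GO:0072006"),
       "organ development above nephron development")
  fact(all(c("GO:0072006", "GO:0072077", "GO:0072088") %in%
             pog_ancestors(pog, "GO:0072283")),
       "metanephric renal vesicle morphogenesis below the three nephron terms")

  mv <- function(kcs, cand, role) is_meaningful(pog, d, kcs, cand, role)$meaningful
  fact("GO:0072009" %in% lowest_common_ancestors(pog, c("GO:0072088", "GO:0072077")),
       "nephron epithelium development is an LCA of the morphogenesis pair")
  fact(!mv(c("GO:0072088", "GO:0072077"), "GO:0072009", "lca"),
       "that LCA is meaningless (depth tie)")
  fact(!mv(c("GO:0072006", "GO:0072088"), "GO:0048513", "lca"),
       "organ development meaningless for nephron dev + epithelium morph")
  fact(mv(c("GO:0072006", "GO:0072088"), "GO:0072283", "tcd"),
       "metanephric TCD meaningful for nephron dev + epithelium morph")
  fact(mv(c("GO:0072088", "GO:0072077"), "GO:0072283", "tcd"),
       "metanephric TCD meaningful for the morphogenesis pair")
  fact(mv(c("GO:0072006", "GO:0072009"), "GO:0048513", "lca"),
       "organ development meaningful for the two development terms")
  fact(!mv(c("GO:0072006", "GO:0072009"), "GO:0072283", "tcd"),
       "metanephric TCD meaningless for the two development terms")

  if (length(failures) > 0) {
    abort(paste0("Example facts violated:\n",
                 paste0("  - ", failures, collapse = "\n")))
  }
  invisible(TRUE)
}

#' @export
print.grank_example <- function(x, ...) {
  cat("<grank_example> nephrogenesis ontology fragment\n")
  print(x$graph)
  cat(sprintf("  %d annotation pairs over %d genes; microarray: %d genes, %d significant\n",
              nrow(x$annotations), length(unique(x$annotations$gene)),
              nrow(x$microarray), sum(x$microarray$significant)))
  invisible(x)
}
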