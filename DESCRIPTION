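Package: gorank
Title: Ranking Genes by Gene Ontology Semantic Relatedness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A search engine for gene sets: given query genes annotated to
    Gene Ontology terms, finds other genes that are semantically related to
    them.  The ontology is converted to a part-of graph (explicit plus
    inferred part-of relations), candidate lowest common ancestors and top
    common descendants of the query annotations are screened with a
    depth-uniqueness rule motivated by existence dependency, and surviving
    terms are ranked by a decay-, proximity-, and cumulative-hypergeometric
    score built from a microarray reference.  Includes readers and writers
    for OBO ontologies, GAF and two-column annotation files, a layered
    random-ontology simulator for property testing, and recall/precision
    evaluation against reference gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    igraph,
    ggplot2,
    generics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
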