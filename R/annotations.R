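#' Read gene-to-term annotations
#'
#' Reads annotations either from a GO Annotation File (GAF 2.x; gene symbol
#' in column 3, term accession in column 5, evidence code in column 7,
#' comment lines starting with `!`) or from a headerless two-column
#' `gene<TAB>term` file.  Pairs referring to terms absent from `graph` are
#' dropped; the number dropped is attached as attribute `n_dropped` and
#' reported.
#'
#' @param file Path to the annotation file, or a character vector of lines.
#' @param format `"tsv"` (two columns) or `"gaf"`.
#' @param graph The companion [go_graph()]; used for referential integrity.
#' @return A tibble of class `go_annotations` with columns `gene`, `term`,
#'   `evidence` (`NA` for TSV input).
#' @examples
#' g <- go_graph(data.frame(term = c("GO:1", "GO:2")),
#'               data.frame(child = "GO:2", parent = "GO:1", relation = "is_a"))
#' parse_annotations(c("geneA\tGO:2", "geneB\tGO:1"), "tsv", g)
#' @export
parse_annotations <- function(file, format = c("tsv", "gaf"), graph) {
  format <- match.arg(format)
  stopifnot(inherits(graph, "go_graph"))
  lines <- read_input_lines(file)
  lines <- lines[trimws(lines) != ""]

  if (format == "gaf") {
    lines <- lines[!startsWith(lines, "!")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(fields, length, integer(1)) >= 7
    if (any(!ok)) {
      abort(sprintf("GAF row %d has fewer than 7 columns",
                    which(!ok)[[1]]))
    }
    ann <- tibble(
      gene = vapply(fields, `[[`, character(1), 3),
      term = vapply(fields, `[[`, character(1), 5),
      evidence = vapply(fields, `[[`, character(1), 7)
    )
  } else {
    # tolerate an optional "gene<TAB>term" header line
    if (length(lines) > 0 && identical(tolower(lines[[1]]), "gene\tterm")) {
      lines <- lines[-1]
    }
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ok <- vapply(fields, length, integer(1)) >= 2
    if (any(!ok)) {
      abort(sprintf("TSV annotation row %d does not have 2 tab-separated columns",
                    which(!ok)[[1]]))
    }
    ann <- tibble(
      gene = vapply(fields, `[[`, character(1), 1),
      term = vapply(fields, `[[`, character(1), 2),
      evidence = NA_character_
    )
  }

  if (any(ann$gene == "")) abort("Empty gene identifier in annotation input.")
  known <- ann$term %in% graph$terms$term
  n_dropped <- sum(!known)
  ann <- distinct(ann[known, ])
  if (nrow(ann) == 0) {
    abort("No annotation pairs survive parsing (all terms unknown or input empty).")
  }
  if (n_dropped > 0) {
    inform(sprintf("Dropped %d annotation pair(s) whose term is not in the graph.",
                   n_dropped))
  }
  structure(ann, n_dropped = n_dropped,
            class = c("go_annotations", class(ann)))
}

read_input_lines <- function(file) {
  if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else if (length(file) == 1 && grepl("\n", file)) {
    strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    as.character(file)
  }
}

#' Build an annotation set from a data frame
#'
#' Convenience constructor used by the simulator and the bundled example:
#' validates gene/term pairs against a graph without going through text.
#'
#' @param df Data frame with columns `gene`, `term` and optionally
#'   `evidence`.
#' @param graph The companion [go_graph()].
#' @return A `go_annotations` tibble.
#' @export
as_go_annotations <- function(df, graph) {
  stopifnot(inherits(graph, "go_graph"))
  df <- as_tibble(df)
  if (!"evidence" %in% names(df)) df$evidence <- NA_character_
  df <- distinct(df[, c("gene", "term", "evidence")])
  unknown <- setdiff(df$term, graph$terms$term)
  if (length(unknown) > 0) {
    abort(paste0("Annotation term(s) not in graph: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  if (any(df$gene == "" | is.na(df$gene))) abort("Gene identifiers must be non-empty.")
  structure(df, n_dropped = 0L, class = c("go_annotations", class(df)))
}

#' Read a microarray reference
#'
#' Reads a tab-separated file with header `gene<TAB>significant` where the
#' significance flag is 0 or 1.  Duplicate genes are collapsed; a gene is
#' significant if any of its rows is flagged.  The universe size `a` and
#' significant count `c` of the term-score formula come from this object.
#'
#' @param file Path or character vector of lines.
#' @return A tibble of class `go_microarray` with columns `gene`,
#'   `significant` (logical).
#' @examples
#' parse_microarray(c("gene\tsignificant", "g1\t1", "g2\t0", "g2\t1"))
#' @export
parse_microarray <- function(file) {
  lines <- read_input_lines(file)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) abort("Empty microarray input.")
  if (identical(tolower(trimws(lines[[1]])), "gene\tsignificant")) {
    lines <- lines[-1]
  }
  if (length(lines) == 0) abort("Microarray input has a header but no rows.")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- vapply(fields, length, integer(1)) >= 2
  if (any(!ok)) {
    abort(sprintf("Microarray row %d does not have 2 tab-separated columns",
                  which(!ok)[[1]]))
  }
  gene <- vapply(fields, `[[`, character(1), 1)
  flag <- vapply(fields, `[[`, character(1), 2)
  if (!all(flag %in% c("0", "1"))) {
    bad <- which(!flag %in% c("0", "1"))[[1]]
    abort(sprintf("Non-binary significance flag \"%s\" at microarray row %d",
                  flag[[bad]], bad))
  }
  tibble(gene = gene, significant = flag == "1") |>
    group_by(.data$gene) |>
    summarise(significant = any(.data$significant), .groups = "drop") |>
    new_microarray()
}

new_microarray <- function(df) {
  structure(df, class = c("go_microarray", class(df)))
}

#' Build a microarray reference from vectors
#'
#' @param genes Character vector: the gene universe.
#' @param significant Character vector: the significant subset, or a logical
#'   vector parallel to `genes`.
#' @return A `go_microarray` tibble.
#' @export
as_go_microarray <- function(genes, significant) {
  genes <- unique(as.character(genes))
  sig <- if (is.logical(significant)) {
    unique(genes[significant])
  } else {
    unique(as.character(significant))
  }
  if (!all(sig %in% genes)) {
    abort("Significant genes must be a subset of the universe.")
  }
  new_microarray(tibble(gene = genes, significant = genes %in% sig))
}

#' Map query genes to their annotation terms
#'
#' Returns, per query gene, the set of terms it is *directly* annotated to
#' (no propagation to ancestors).  These per-gene terms are the keyword
#' contexts the search operates on.  Duplicate query genes are removed
#' preserving first occurrence; genes without any annotation are reported
#' via a warning and the `unannotated` attribute.
#'
#' @param genes Character vector of query gene identifiers (case-sensitive,
#'   treated as opaque strings).
#' @param annotations A [parse_annotations()] result.
#' @param params A [grank_params()]; with `iea_filter = TRUE`, annotations
#'   with evidence code `"IEA"` are ignored.
#' @return A tibble with columns `gene`, `term`, one row per keyword
#'   context, ordered by query position then term.
#' @examples
#' g <- go_graph(data.frame(term = c("GO:1", "GO:2")),
#'               data.frame(child = "GO:2", parent = "GO:1", relation = "is_a"))
#' ann <- parse_annotations("JAG1\tGO:2", "tsv", g)
#' map_query_to_kcs("JAG1", ann)
#' @export
map_query_to_kcs <- function(genes, annotations, params = grank_params()) {
  stopifnot(inherits(annotations, "go_annotations"))
  genes <- as.character(genes)
  if (length(genes) == 0) abort("Query must contain at least one gene.")
  genes <- genes[!duplicated(genes)]
  ann <- annotations
  if (params$iea_filter) {
    ann <- filter(ann, is.na(.data$evidence) | .data$evidence != "IEA")
  }
  kcs <- ann |>
    filter(.data$gene %in% genes) |>
    select("gene", "term") |>
    distinct() |>
    mutate(gene = factor(.data$gene, levels = genes)) |>
    arrange(.data$gene, .data$term) |>
    mutate(gene = as.character(.data$gene))
  missing <- setdiff(genes, kcs$gene)
  if (length(missing) == length(genes)) {
    abort("Query unanswerable: no query gene has any annotation.")
  }
  if (length(missing) > 0) {
    warn(paste0("Query gene(s) without annotation: ",
                paste(missing, collapse = ", ")))
  }
  structure(kcs, unannotated = missing)
}

#' Write annotations as TSV or GAF
#'
#' Serialises a `go_annotations` tibble to the formats read by
#' [parse_annotations()].  The GAF writer emits minimal 17-column rows
#' (database, id, symbol, qualifier, term, reference, evidence, ...), with
#' the evidence code defaulting to `"TAS"` when unknown.
#'
#' @param annotations A `go_annotations` tibble.
#' @param file Optional path.
#' @param format `"tsv"` or `"gaf"`.
#' @return The serialised lines, invisibly.
#' @export
write_annotations <- function(annotations, file = NULL,
                              format = c("tsv", "gaf")) {
  format <- match.arg(format)
  stopifnot(inherits(annotations, "go_annotations"))
  if (format == "tsv") {
    lines <- sprintf("%s\t%s", annotations$gene, annotations$term)
  } else {
    ev <- ifelse(is.na(annotations$evidence), "TAS", annotations$evidence)
    lines <- vapply(seq_len(nrow(annotations)), function(i) {
      paste(c("DB", annotations$gene[[i]], annotations$gene[[i]], "",
              annotations$term[[i]], "REF:0", ev[[i]], "", "P", "", "",
              "gene", "taxon:0", "20240101", "DB", "", ""),
            collapse = "\t")
    }, character(1))
    lines <- c("!gaf-version: 2.2", lines)
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
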