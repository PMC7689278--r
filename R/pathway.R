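# Directed pathway graphs and their readers.

#' Construct a directed pathway graph
#'
#' A pathway is a directed gene graph (KEGG-style): nodes are gene
#' identifiers (opaque, case-sensitive strings) and edges are ordered pairs
#' with an optional relation label (e.g. "activation"). Self-loops are
#' rejected and every edge endpoint must be a node.
#'
#' @param edges A data.frame with columns `source`, `target` and optionally
#'   `relation`, or a 2/3-column matrix-like coercible to one.
#' @param nodes Optional character vector of node names; defaults to the
#'   union of edge endpoints. Extra isolated nodes are allowed.
#' @param name Pathway identifier.
#' @return An object of class `pathway_graph` with elements `name`, `nodes`
#'   and `edges` (data.frame source/target/relation).
#' @export
pathway_graph <- function(edges, nodes = NULL, name = "pathway") {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (ncol(edges) < 2L) stop("edges must have at least two columns (source, target)")
  names(edges)[1:2] <- c("source", "target")
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  if (!"relation" %in% names(edges)) {
    edges$relation <- if (ncol(edges) >= 3L) as.character(edges[[3L]]) else NA_character_
  }
  edges <- edges[, c("source", "target", "relation")]
  if (any(edges$source == edges$target)) {
    stop("self-loops are not allowed in a pathway graph")
  }
  if (is.null(nodes)) {
    nodes <- unique(c(edges$source, edges$target))
  } else {
    nodes <- as.character(nodes)
    missing <- setdiff(unique(c(edges$source, edges$target)), nodes)
    if (length(missing)) {
      stop("edges reference genes absent from `nodes`: ", paste(missing, collapse = ", "))
    }
  }
  structure(list(name = name, nodes = nodes, edges = edges),
            class = "pathway_graph")
}

#' @export
print.pathway_graph <- function(x, ...) {
  cat(sprintf("Pathway graph '%s': %d nodes, %d directed edges\n",
              x$name, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a pathway from an edge-list TSV
#'
#' Expects a header with columns `source`, `target` and optionally
#' `relation` (extra columns are ignored).
#'
#' @param path File path.
#' @param name Pathway name; defaults to the file name without extension.
#' @return A [pathway_graph()].
#' @export
read_pathway_tsv <- function(path, name = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("source", "target") %in% names(tab))) {
    names(tab)[1:2] <- c("source", "target")
  }
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pathway_graph(tab[, intersect(c("source", "target", "relation"), names(tab))],
                name = name)
}

#' Read a pathway from a GML file
#'
#' Thin wrapper over [igraph::read_graph()]; node labels (or names) become
#' gene identifiers.
#' @param path File path.
#' @param name Pathway name; defaults to the file name.
#' @return A [pathway_graph()].
#' @export
read_pathway_gml <- function(path, name = NULL) {
  g <- igraph::read_graph(path, format = "gml")
  labs <- igraph::vertex_attr(g, "label") %||% igraph::vertex_attr(g, "name")
  if (is.null(labs)) labs <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  pathway_graph(data.frame(source = labs[el[, 1]], target = labs[el[, 2]],
                           stringsAsFactors = FALSE),
                nodes = labs, name = name)
}

#' Read a minimal KGML pathway file
#'
#' Parses only `entry` elements of type "gene" and `relation` elements
#' between them (subtype name, when present, becomes the relation label).
#' Entries whose name lists several genes contribute the first identifier.
#' Requires the xml2 package.
#'
#' @param path KGML file path.
#' @return A [pathway_graph()].
#' @export
read_pathway_kgml <- function(path) {
  if (!requireNamespace("xml2", quietly = TRUE)) {
    stop("reading KGML requires the xml2 package")
  }
  doc <- xml2::read_xml(path)
  entries <- xml2::xml_find_all(doc, ".//entry[@type='gene']")
  ids <- xml2::xml_attr(entries, "id")
  gene <- vapply(xml2::xml_attr(entries, "name"),
                 function(s) strsplit(s, "[[:space:]]+")[[1]][1], character(1))
  id2gene <- stats::setNames(gene, ids)
  rels <- xml2::xml_find_all(doc, ".//relation")
  rows <- lapply(rels, function(r) {
    e1 <- xml2::xml_attr(r, "entry1"); e2 <- xml2::xml_attr(r, "entry2")
    if (!(e1 %in% ids && e2 %in% ids)) return(NULL)
    sub <- xml2::xml_find_first(r, "./subtype")
    data.frame(source = id2gene[[e1]], target = id2gene[[e2]],
               relation = if (inherits(sub, "xml_missing")) NA_character_
                          else xml2::xml_attr(sub, "name"),
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, rows)
  if (is.null(edges)) edges <- data.frame(source = character(), target = character(),
                                          relation = character())
  edges <- edges[edges$source != edges$target, , drop = FALSE]
  name <- xml2::xml_attr(xml2::xml_root(doc), "name") %||% basename(path)
  pathway_graph(edges, nodes = unique(unname(gene)), name = name)
}

#' Write a pathway as an edge-list TSV
#' @param pathway A [pathway_graph()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pathway_tsv <- function(pathway, path) {
  utils::write.table(pathway$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
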