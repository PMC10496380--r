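# sniff CSV vs TSV from the header line
.read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first) || !nzchar(first)) {
    stop(sprintf("'%s' is empty", path), call. = FALSE)
  }
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    strip.white = TRUE)
}

#' Read a two-column mapping table
#'
#' Reads an ingredient-to-target or target-to-pathway relation from a
#' two-column CSV or TSV file with a header (the delimiter is sniffed from
#' the header line). Ids are whitespace-trimmed; duplicate rows are
#' collapsed with a message. Normalisation stops at trimming — ids are
#' otherwise taken verbatim, so case conventions are the caller's contract.
#'
#' @param path file path.
#' @param kind `"ingredient-target"` or `"target-pathway"`; only used in
#'   messages and error text.
#' @return named list mapping each first-column id to the sorted unique
#'   character vector of second-column ids.
#' @export
read_mapping_table <- function(path, kind = c("ingredient-target", "target-pathway")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    stop(sprintf("%s table not found: '%s'", kind, path), call. = FALSE)
  }
  df <- .read_delim_auto(path)
  if (ncol(df) != 2L) {
    stop(sprintf("%s table '%s' must have exactly 2 columns, found %d",
                 kind, path, ncol(df)), call. = FALSE)
  }
  if (nrow(df) == 0L) {
    stop(sprintf("%s table '%s' has no data rows", kind, path), call. = FALSE)
  }
  a <- trimws(as.character(df[[1L]]))
  b <- trimws(as.character(df[[2L]]))
  bad <- which(!nzchar(a) | !nzchar(b))
  if (length(bad)) {
    stop(sprintf("%s table '%s': empty id at data line %d",
                 kind, path, bad[1L]), call. = FALSE)
  }
  dup <- duplicated(paste(a, b, sep = "\r"))
  if (any(dup)) {
    message(sprintf("collapsed %d duplicate row(s) in %s", sum(dup), path))
  }
  .as_mapping(data.frame(a = a[!dup], b = b[!dup]), kind)
}

#' Write a mapping as a two-column CSV
#'
#' The inverse of [read_mapping_table()]: one row per annotation pair, in
#' the dialect the readers consume, so generated instances round-trip
#' through the pipeline.
#'
#' @param mapping named list (id to character vector).
#' @param path output path.
#' @param columns length-2 character vector of column names.
#' @return `path`, invisibly.
#' @export
write_mapping_table <- function(mapping, path,
                                columns = c("ingredient", "target")) {
  stopifnot(is.list(mapping), length(columns) == 2L)
  df <- data.frame(
    a = rep(names(mapping), lengths(mapping)),
    b = unlist(mapping, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  names(df) <- columns
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Pajek encodes no general node attributes; node type rides on the vertex
# shape (ellipse = ingredient, box = pathway), which Pajek itself renders
.pajek_shape <- c(ingredient = "ellipse", pathway = "box")

#' Write a network in Pajek .net format
#'
#' 1-based vertex numbering, quoted labels, `*Vertices` and `*Edges`
#' sections. Node type is encoded as the vertex shape (`ellipse` for
#' ingredients, `box` for pathways) so [read_pajek()] can recover it.
#' Vertices are written in the network's sorted node order.
#'
#' @param net an `itp_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pajek <- function(net, path) {
  stopifnot(inherits(net, "itp_network"))
  idx <- stats::setNames(seq_len(n_nodes(net)), net$nodes$id)
  lines <- c(
    sprintf("*Vertices %d", n_nodes(net)),
    sprintf("%d \"%s\" %s", idx, net$nodes$id, .pajek_shape[net$nodes$type]),
    "*Edges",
    if (n_edges(net)) sprintf("%d %d", idx[net$edges$from], idx[net$edges$to])
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a network from Pajek .net format
#'
#' Reads the dialect produced by [write_pajek()] (and plain `*Vertices` /
#' `*Edges` files without shapes, in which case every node is typed as an
#' ingredient).
#'
#' @param path file path.
#' @param name network name to stamp on the result.
#' @return an `itp_network`.
#' @export
read_pajek <- function(path, name = "IPI") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vhead <- grep("^\\*Vertices", lines, ignore.case = TRUE)
  ehead <- grep("^\\*(Edges|Arcs)", lines, ignore.case = TRUE)
  if (length(vhead) != 1L || length(ehead) != 1L) {
    stop(sprintf("'%s' is not a Pajek .net file", path), call. = FALSE)
  }
  n <- as.integer(sub("^\\*Vertices\\s+", "", lines[vhead], ignore.case = TRUE))
  vlines <- lines[(vhead + 1L):(ehead - 1L)]
  if (length(vlines) != n) {
    stop(sprintf("'%s': expected %d vertex lines, found %d",
                 path, n, length(vlines)), call. = FALSE)
  }
  m <- regmatches(vlines, regexec('^\\s*(\\d+)\\s+"([^"]*)"\\s*(\\S*)', vlines))
  if (any(lengths(m) != 4L)) {
    stop(sprintf("'%s': malformed vertex line", path), call. = FALSE)
  }
  vid <- as.integer(vapply(m, `[[`, character(1L), 2L))
  labels <- vapply(m, `[[`, character(1L), 3L)
  shapes <- vapply(m, `[[`, character(1L), 4L)
  types <- ifelse(shapes == "box", "pathway", "ingredient")
  labels <- labels[order(vid)]
  types <- types[order(vid)]
  edges <- if (ehead < length(lines)) {
    el <- lines[(ehead + 1L):length(lines)]
    parts <- strsplit(trimws(el), "\\s+")
    data.frame(
      from = labels[as.integer(vapply(parts, `[[`, character(1L), 1L))],
      to = labels[as.integer(vapply(parts, `[[`, character(1L), 2L))],
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  }
  itp_network(data.frame(id = labels, type = types, stringsAsFactors = FALSE),
              edges, name)
}

.xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

#' Write a network in GraphML format
#'
#' Undirected graph with a `node_type` node attribute.
#'
#' @param net an `itp_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "itp_network"))
  ids <- .xml_escape(net$nodes$id)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '  <key id="d0" for="node" attr.name="node_type" attr.type="string"/>',
    sprintf('  <graph id="%s" edgedefault="undirected">', .xml_escape(net$name)),
    sprintf('    <node id="%s"><data key="d0">%s</data></node>',
            ids, net$nodes$type),
    if (n_edges(net)) {
      sprintf('    <edge source="%s" target="%s"/>',
              .xml_escape(net$edges$from), .xml_escape(net$edges$to))
    },
    "  </graph>",
    "</graphml>"
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a network from GraphML format
#'
#' Expects an undirected graph; the `node_type` attribute is recovered when
#' present (nodes without one are typed as ingredients).
#'
#' @param path file path.
#' @param name network name; defaults to the GraphML graph id when set.
#' @return an `itp_network`.
#' @export
read_graphml <- function(path, name = NULL) {
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
  graph <- xml2::xml_find_first(doc, ".//g:graph", ns)
  if (is.na(xml2::xml_attr(graph, "id")) && is.null(name)) {
    name <- "IPI"
  } else if (is.null(name)) {
    name <- xml2::xml_attr(graph, "id")
  }
  node_els <- xml2::xml_find_all(graph, "./g:node", ns)
  ids <- xml2::xml_attr(node_els, "id")
  types <- vapply(node_els, function(el) {
    d <- xml2::xml_find_first(el, "./g:data", ns)
    if (inherits(d, "xml_missing")) "ingredient" else xml2::xml_text(d)
  }, character(1L))
  edge_els <- xml2::xml_find_all(graph, "./g:edge", ns)
  edges <- data.frame(
    from = xml2::xml_attr(edge_els, "source"),
    to = xml2::xml_attr(edge_els, "target"),
    stringsAsFactors = FALSE
  )
  itp_network(data.frame(id = ids, type = types, stringsAsFactors = FALSE),
              edges, name)
}

#' Write a network in a given format
#'
#' @param net an `itp_network`.
#' @param path output path.
#' @param format `"pajek"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("pajek", "graphml")) {
  format <- match.arg(format)
  switch(format, pajek = write_pajek(net, path), graphml = write_graphml(net, path))
}

#' Export a metrics report as CSV tables
#'
#' Writes the per-node statistics, the degree distribution, and the
#' clustering spectrum of one report as plain CSV files
#' (`<name>_nodes.csv`, `<name>_degree_distribution.csv`,
#' `<name>_clustering_spectrum.csv`) for downstream plotting.
#'
#' @param report an `itp_metrics` object.
#' @param dir output directory (created if needed).
#' @return character vector of the files written, invisibly.
#' @export
write_metrics_report <- function(report, dir) {
  stopifnot(inherits(report, "itp_metrics"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  base <- file.path(dir, tolower(report$network_name))
  files <- c(
    nodes = paste0(base, "_nodes.csv"),
    degdist = paste0(base, "_degree_distribution.csv"),
    spectrum = paste0(base, "_clustering_spectrum.csv")
  )
  utils::write.csv(report$per_node, files["nodes"], row.names = FALSE)
  utils::write.csv(report$degree_distribution, files["degdist"], row.names = FALSE)
  utils::write.csv(report$clustering_spectrum, files["spectrum"], row.names = FALSE)
  invisible(files)
}
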