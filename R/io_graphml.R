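#' @title Nested GraphML reader/writer
#' @description Compound structure is encoded the standard GraphML way, as a
#'   nested `<graph>` element under the owning compound's `<node>`. Custom
#'   `<data>` keys carry geometry (`x`, `y`, `w`, `h`), state flags
#'   (`hidden`, `highlighted`, `collapsed`, `label`) and the meta-edge
#'   machinery: an edge's `kind` and `original_ref`, plus `archived="true"`
#'   on the original edges currently represented by meta edges (serialised at
#'   the top level so they survive round trips). The nested graph under a
#'   collapsed node is its subgraph store: positions inside are relative to
#'   the compound's centre. Output is deterministic (ids sorted, `%.10g`
#'   numbers), so re-serialising a freshly read file is byte-identical.
#' @name io-graphml
NULL

CG_GRAPHML_NODE_KEYS <- c("x", "y", "w", "h", "hidden", "highlighted",
                          "collapsed", "label")
CG_GRAPHML_EDGE_KEYS <- c("kind", "original_ref", "ehidden", "ehighlighted",
                          "archived")

cg_num <- function(x) sprintf("%.10g", x)

cg_xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x <- gsub("\"", "&quot;", x, fixed = TRUE)
  x
}

#' Write a compound graph as nested GraphML
#'
#' @inheritParams collapse_node
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(graph, path) {
  out <- c('<?xml version="1.0" encoding="UTF-8"?>',
           '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">')
  for (k in CG_GRAPHML_NODE_KEYS)
    out <- c(out, sprintf('  <key id="%s" for="node" attr.name="%s"/>', k, k))
  for (k in CG_GRAPHML_EDGE_KEYS)
    out <- c(out, sprintf('  <key id="%s" for="edge" attr.name="%s"/>', k, k))
  out <- c(out, '  <graph id="root" edgedefault="undirected">')
  out <- c(out, cg_graphml_level(graph$nodes, graph$edges, parent = NA_character_,
                                 indent = "    "))
  for (eid in sort(names(graph$archived_originals))) {
    out <- c(out, cg_graphml_edge(graph$archived_originals[[eid]],
                                  indent = "    ", archived = TRUE))
  }
  out <- c(out, "  </graph>", "</graphml>")
  writeLines(out, path)
  invisible(path)
}

## serialize one nesting level: nodes owned by `parent` plus, at the root
## call, the edges of the supplied edge set whose endpoints live anywhere
cg_graphml_level <- function(nodes, edges, parent, indent) {
  out <- character()
  ids <- sort(names(nodes))
  for (id in ids) {
    nd <- nodes[[id]]
    same <- identical(nd$parent, parent) || (is.na(nd$parent) && is.na(parent))
    if (!same) next
    out <- c(out, sprintf('%s<node id="%s">', indent, cg_xml_escape(id)))
    dat <- c(x = cg_num(nd$x), y = cg_num(nd$y), w = cg_num(nd$width),
             h = cg_num(nd$height),
             hidden = tolower(nd$hidden), highlighted = tolower(nd$highlighted),
             collapsed = tolower(nd$collapsed))
    if (!is.na(nd$label)) dat <- c(dat, label = cg_xml_escape(nd$label))
    for (k in names(dat))
      out <- c(out, sprintf('%s  <data key="%s">%s</data>', indent, k, dat[[k]]))
    if (nd$collapsed) {
      out <- c(out, sprintf('%s  <graph id="%s::store" edgedefault="undirected">',
                            indent, cg_xml_escape(id)))
      out <- c(out, cg_graphml_level(nd$store$nodes, nd$store$edges,
                                     parent = id, indent = paste0(indent, "    ")))
      for (eid in sort(names(nd$store$edges)))
        out <- c(out, cg_graphml_edge(nd$store$edges[[eid]],
                                      indent = paste0(indent, "    ")))
      out <- c(out, sprintf('%s  </graph>', indent))
    } else if (any(vapply(nodes, function(n) identical(n$parent, id), logical(1)))) {
      out <- c(out, sprintf('%s  <graph id="%s::children" edgedefault="undirected">',
                            indent, cg_xml_escape(id)))
      out <- c(out, cg_graphml_level(nodes, list(), parent = id,
                                     indent = paste0(indent, "    ")))
      out <- c(out, sprintf('%s  </graph>', indent))
    }
    out <- c(out, sprintf('%s</node>', indent))
  }
  if (is.na(parent)) {
    for (eid in sort(names(edges)))
      out <- c(out, cg_graphml_edge(edges[[eid]], indent))
  }
  out
}

cg_graphml_edge <- function(ed, indent, archived = FALSE) {
  out <- sprintf('%s<edge id="%s" source="%s" target="%s">',
                 indent, cg_xml_escape(ed$id), cg_xml_escape(ed$source),
                 cg_xml_escape(ed$target))
  dat <- c(kind = ed$kind)
  if (!is.na(ed$original_ref)) dat <- c(dat, original_ref = ed$original_ref)
  dat <- c(dat, ehidden = tolower(ed$hidden), ehighlighted = tolower(ed$highlighted))
  if (archived) dat <- c(dat, archived = "true")
  for (k in names(dat))
    out <- c(out, sprintf('%s  <data key="%s">%s</data>', indent, k,
                          cg_xml_escape(dat[[k]])))
  c(out, sprintf('%s</edge>', indent))
}

#' Read a compound graph from nested GraphML
#'
#' The file is validated after parsing; structural violations are raised as
#' an error listing each violation.
#'
#' @param path path to a GraphML file written by [write_graphml()] (or any
#'   nested GraphML using the same data keys).
#' @return a valid `compound_graph`.
#' @export
read_graphml <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  root <- xml2::xml_find_first(doc, "./graph")
  if (inherits(root, "xml_missing")) stop("no <graph> element in ", path)
  g <- new_compound_graph()
  parsed <- cg_graphml_parse_graph(root, parent = NA_character_, in_store = FALSE)
  g$nodes <- parsed$nodes
  for (ed in parsed$edges) {
    if (isTRUE(ed$archived)) {
      ed$archived <- NULL
      g$archived_originals[[ed$id]] <- ed
    } else {
      ed$archived <- NULL
      g$edges[[ed$id]] <- ed
    }
  }
  v <- validate_graph(g)
  if (length(v))
    stop("invalid graph in ", path, ": ",
         paste(vapply(v, function(x) paste0(x$code, "(", x$subject, ")"),
                      ""), collapse = ", "))
  g
}

cg_graphml_data <- function(el) {
  kids <- xml2::xml_find_all(el, "./data")
  stats::setNames(as.list(xml2::xml_text(kids)),
                  xml2::xml_attr(kids, "key"))
}

cg_graphml_parse_node <- function(el, parent) {
  dat <- cg_graphml_data(el)
  getn <- function(k, d) if (is.null(dat[[k]])) d else as.numeric(dat[[k]])
  getb <- function(k) identical(dat[[k]], "true")
  nd <- cg_node_record(
    id = xml2::xml_attr(el, "id"), parent = parent,
    x = getn("x", 0), y = getn("y", 0),
    width = getn("w", CG_DEFAULT_DIM), height = getn("h", CG_DEFAULT_DIM),
    hidden = getb("hidden"), highlighted = getb("highlighted"),
    collapsed = getb("collapsed"),
    label = if (is.null(dat$label)) NA_character_ else dat$label)
  sub <- xml2::xml_find_first(el, "./graph")
  list(node = nd, subgraph = if (inherits(sub, "xml_missing")) NULL else sub)
}

## returns list(nodes = named flat list incl. nested levels, edges = list)
cg_graphml_parse_graph <- function(gel, parent, in_store) {
  nodes <- list(); edges <- list()
  for (el in xml2::xml_find_all(gel, "./node")) {
    pn <- cg_graphml_parse_node(el, parent)
    nd <- pn$node
    if (!is.null(pn$subgraph)) {
      sub <- cg_graphml_parse_graph(pn$subgraph, parent = nd$id,
                                    in_store = in_store || nd$collapsed)
      if (nd$collapsed) {
        nd$store <- list(nodes = sub$nodes, edges = list())
        for (ed in sub$edges) {
          ed$archived <- NULL
          nd$store$edges[[ed$id]] <- ed
        }
      } else {
        nodes <- c(nodes, sub$nodes)
        edges <- c(edges, sub$edges)
      }
    }
    nodes[[nd$id]] <- nd
  }
  ## active nodes come before their descendants for stable ordering
  for (el in xml2::xml_find_all(gel, "./edge")) {
    dat <- cg_graphml_data(el)
    ed <- cg_edge_record(
      id = xml2::xml_attr(el, "id"),
      source = xml2::xml_attr(el, "source"),
      target = xml2::xml_attr(el, "target"),
      kind = if (is.null(dat$kind)) "original" else dat$kind,
      original_ref = if (is.null(dat$original_ref)) NA_character_ else dat$original_ref,
      hidden = identical(dat$ehidden, "true"),
      highlighted = identical(dat$ehighlighted, "true"))
    ed$archived <- identical(dat$archived, "true")
    edges[[ed$id]] <- ed
  }
  list(nodes = nodes, edges = edges)
}
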