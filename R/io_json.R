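#' @title JSON elements reader/writer
#' @description A flat elements-list dialect interoperable with web graph
#'   libraries: each element carries `group` (`"nodes"`/`"edges"`) and a
#'   `data` object (`id`, optional `parent` for nodes, `source`/`target` and
#'   the meta-edge fields for edges), nodes additionally `position` and
#'   `dimensions`. The document is an object with `elements` plus an
#'   `archived_originals` array; the store of a collapsed node is embedded
#'   under the node as `store` (positions relative to the compound centre).
#'   Hidden elements are written with a `style.display = "none"` and/or
#'   `style.visibility = "hidden"` attribute depending on options; unknown
#'   `data` fields are preserved opaquely across round trips.
#' @name io-json
NULL

cg_json_node_element <- function(nd, options) {
  dat <- list(id = nd$id)
  if (!is.na(nd$parent)) dat$parent <- nd$parent
  if (!is.na(nd$label)) dat$label <- nd$label
  if (nd$collapsed) dat$collapsed <- TRUE
  if (nd$highlighted) dat$highlighted <- TRUE
  if (!is.null(nd$extra)) dat <- c(dat, nd$extra)
  el <- list(group = "nodes", data = dat,
             position = list(x = nd$x, y = nd$y),
             dimensions = list(w = nd$width, h = nd$height))
  el <- cg_json_hidden_style(el, nd$hidden, options)
  if (nd$collapsed)
    el$store <- list(
      nodes = lapply(nd$store$nodes[sort(names(nd$store$nodes))],
                     cg_json_node_element, options = options),
      edges = lapply(nd$store$edges[sort(names(nd$store$edges))],
                     cg_json_edge_element, options = options))
  el
}

cg_json_edge_element <- function(ed, options, archived = FALSE) {
  dat <- list(id = ed$id, source = ed$source, target = ed$target)
  if (ed$kind != "original") dat$kind <- ed$kind
  if (!is.na(ed$original_ref)) dat$original_ref <- ed$original_ref
  if (ed$highlighted) dat$highlighted <- TRUE
  if (archived) dat$archived <- TRUE
  if (!is.null(ed$extra)) dat <- c(dat, ed$extra)
  cg_json_hidden_style(list(group = "edges", data = dat), ed$hidden, options)
}

cg_json_hidden_style <- function(el, hidden, options) {
  if (!hidden) return(el)
  style <- list()
  if (options$set_display_on_hide) style$display <- "none"
  if (options$set_visibility_on_hide) style$visibility <- "hidden"
  if (!length(style)) style$display <- "none"
  el$style <- style
  el
}

#' Write a compound graph to the JSON elements dialect
#'
#' @inheritParams collapse_node
#' @param path output file path.
#' @param options a [cg_options()] list; `set_display_on_hide` /
#'   `set_visibility_on_hide` choose which style attribute hidden elements
#'   receive.
#' @return `path`, invisibly.
#' @export
write_json_graph <- function(graph, path, options = cg_options()) {
  elements <- c(
    lapply(graph$nodes[sort(names(graph$nodes))], cg_json_node_element,
           options = options),
    lapply(graph$edges[sort(names(graph$edges))], cg_json_edge_element,
           options = options))
  doc <- list(
    elements = unname(elements),
    archived_originals = unname(
      lapply(graph$archived_originals[sort(names(graph$archived_originals))],
             cg_json_edge_element, options = options, archived = TRUE)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a compound graph from the JSON elements dialect
#'
#' Accepts either the document object written by [write_json_graph()] or a
#' bare elements array. Validates after parsing and raises on violations.
#'
#' @param path path to a JSON file.
#' @return a valid `compound_graph`.
#' @export
read_json_graph <- function(path) {
  doc <- jsonlite::read_json(path)
  elements <- if (!is.null(doc$elements)) doc$elements else doc
  g <- new_compound_graph()
  for (el in elements) {
    if (identical(el$group, "edges") ||
        (!is.null(el$data$source) && is.null(el$group))) {
      ed <- cg_json_parse_edge(el)
      g$edges[[ed$id]] <- ed
    } else {
      nd <- cg_json_parse_node(el)
      g$nodes[[nd$id]] <- nd
    }
  }
  for (el in doc$archived_originals) {
    ed <- cg_json_parse_edge(el)
    g$archived_originals[[ed$id]] <- ed
  }
  g$highlight_active <- any(vapply(g$nodes, `[[`, logical(1), "highlighted")) ||
    any(vapply(g$edges, `[[`, logical(1), "highlighted"))
  v <- validate_graph(g)
  if (length(v))
    stop("invalid graph in ", path, ": ",
         paste(vapply(v, function(x) paste0(x$code, "(", x$subject, ")"),
                      ""), collapse = ", "))
  g
}

CG_JSON_KNOWN_NODE_FIELDS <- c("id", "parent", "label", "collapsed",
                               "highlighted", "hidden")
CG_JSON_KNOWN_EDGE_FIELDS <- c("id", "source", "target", "kind",
                               "original_ref", "highlighted", "hidden",
                               "archived")

cg_json_hidden_of <- function(el) {
  isTRUE(el$data$hidden) ||
    identical(el$style$display, "none") ||
    identical(el$style$visibility, "hidden")
}

cg_json_parse_node <- function(el) {
  dat <- el$data
  if (is.null(dat$id)) stop("node element without data.id")
  nd <- cg_node_record(
    id = dat$id,
    parent = if (is.null(dat$parent)) NA_character_ else dat$parent,
    x = if (is.null(el$position$x)) 0 else el$position$x,
    y = if (is.null(el$position$y)) 0 else el$position$y,
    width = if (is.null(el$dimensions$w)) CG_DEFAULT_DIM else el$dimensions$w,
    height = if (is.null(el$dimensions$h)) CG_DEFAULT_DIM else el$dimensions$h,
    hidden = cg_json_hidden_of(el),
    highlighted = isTRUE(dat$highlighted),
    collapsed = isTRUE(dat$collapsed),
    label = if (is.null(dat$label)) NA_character_ else dat$label)
  extra <- dat[setdiff(names(dat), CG_JSON_KNOWN_NODE_FIELDS)]
  if (length(extra)) nd$extra <- extra
  if (nd$collapsed) {
    store <- cg_empty_store()
    for (sel in el$store$nodes) {
      snd <- cg_json_parse_node(sel)
      store$nodes[[snd$id]] <- snd
    }
    for (sel in el$store$edges) {
      sed <- cg_json_parse_edge(sel)
      store$edges[[sed$id]] <- sed
    }
    nd$store <- store
  }
  nd
}

cg_json_parse_edge <- function(el) {
  dat <- el$data
  if (is.null(dat$id) || is.null(dat$source) || is.null(dat$target))
    stop("edge element without id/source/target")
  ed <- cg_edge_record(
    id = dat$id, source = dat$source, target = dat$target,
    kind = if (is.null(dat$kind)) "original" else dat$kind,
    original_ref = if (is.null(dat$original_ref)) NA_character_ else dat$original_ref,
    hidden = cg_json_hidden_of(el),
    highlighted = isTRUE(dat$highlighted))
  extra <- dat[setdiff(names(dat), CG_JSON_KNOWN_EDGE_FIELDS)]
  if (length(extra)) ed$extra <- extra
  ed
}
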