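#' @title Compound graph model
#' @description Core in-memory representation of compound (nested) graphs:
#'   nodes V, adjacency edges E and an inclusion relation F encoded through
#'   per-node `parent` fields. The inclusion relation must form a rooted tree
#'   (rooted at an implicit virtual root that is never materialised), and no
#'   adjacency edge may connect a node to one of its ancestors or descendants.
#' @name compound_graph-model
#' @keywords internal
NULL

CG_DEFAULT_DIM <- 30
CG_COMPOUND_MARGIN <- 10
CG_COLLAPSED_DIM <- 30

cg_node_record <- function(id, parent = NA_character_, x = 0, y = 0,
                           width = CG_DEFAULT_DIM, height = CG_DEFAULT_DIM,
                           hidden = FALSE, highlighted = FALSE,
                           collapsed = FALSE, store = NULL,
                           label = NA_character_) {
  list(id = as.character(id), parent = as.character(parent),
       x = as.numeric(x), y = as.numeric(y),
       width = as.numeric(width), height = as.numeric(height),
       hidden = isTRUE(hidden), highlighted = isTRUE(highlighted),
       collapsed = isTRUE(collapsed), store = store,
       label = as.character(label))
}

cg_edge_record <- function(id, source, target, kind = "original",
                           original_ref = NA_character_, hidden = FALSE,
                           highlighted = FALSE) {
  stopifnot(kind %in% c("original", "meta"))
  list(id = as.character(id), source = as.character(source),
       target = as.character(target), kind = kind,
       original_ref = as.character(original_ref),
       hidden = isTRUE(hidden), highlighted = isTRUE(highlighted))
}

cg_empty_store <- function() list(nodes = list(), edges = list())

new_compound_graph <- function(nodes = list(), edges = list(),
                               archived_originals = list(),
                               highlight_active = FALSE) {
  structure(list(nodes = nodes, edges = edges,
                 archived_originals = archived_originals,
                 highlight_active = highlight_active),
            class = "compound_graph")
}

#' Build a compound graph from node and edge descriptors
#'
#' Nodes are described by an `id`, an optional `parent` (the id of the owning
#' compound node; absent or `NA` means the node lives in the root graph),
#' optional geometry (`x`, `y`, `width`, `height`) and an optional `label`.
#' Edges are described by `source` and `target` ids and an optional `id`.
#' Undefined geometry defaults to a 30x30 box centred at the origin, so that
#' construction is deterministic; compound node geometry is always derived
#' from the bounding box of its visible children plus a 10-unit margin.
#'
#' @param node_specs a data.frame (or list of lists) with at least an `id`
#'   column; optional columns `parent`, `x`, `y`, `width`, `height`, `label`.
#' @param edge_specs a data.frame (or list of lists) with `source` and
#'   `target` columns and an optional `id` column.
#' @return an object of class `compound_graph` passing [validate_graph()]
#'   with zero violations.
#' @examples
#' g <- build_graph(
#'   data.frame(id = c("p", "a", "b"), parent = c(NA, "p", "p")),
#'   data.frame(source = "a", target = "b")
#' )
#' length(g$nodes)
#' @export
build_graph <- function(node_specs = NULL, edge_specs = NULL) {
  nspecs <- cg_coerce_specs(node_specs)
  especs <- cg_coerce_specs(edge_specs)
  g <- new_compound_graph()
  for (sp in nspecs) {
    if (is.null(sp$id) || is.na(sp$id)) stop("node descriptor without id")
    id <- as.character(sp$id)
    if (!is.null(g$nodes[[id]])) stop("duplicate node id: ", id)
    g$nodes[[id]] <- cg_node_record(
      id = id,
      parent = if (is.null(sp$parent)) NA_character_ else sp$parent,
      x = if (is.null(sp$x) || is.na(sp$x)) 0 else sp$x,
      y = if (is.null(sp$y) || is.na(sp$y)) 0 else sp$y,
      width = if (is.null(sp$width) || is.na(sp$width)) CG_DEFAULT_DIM else sp$width,
      height = if (is.null(sp$height) || is.na(sp$height)) CG_DEFAULT_DIM else sp$height,
      label = if (is.null(sp$label)) NA_character_ else sp$label)
  }
  for (nd in g$nodes) {
    if (!is.na(nd$parent) && is.null(g$nodes[[nd$parent]]))
      stop("unknown parent id: ", nd$parent)
  }
  cg_check_parent_acyclic(g)
  auto <- 0L
  for (sp in especs) {
    if (is.null(sp$source) || is.null(sp$target))
      stop("edge descriptor without source/target")
    s <- as.character(sp$source); t <- as.character(sp$target)
    if (is.null(g$nodes[[s]])) stop("unknown edge endpoint: ", s)
    if (is.null(g$nodes[[t]])) stop("unknown edge endpoint: ", t)
    if (identical(s, t)) stop("self loops are not allowed: ", s)
    if (cg_is_relative(g, s, t))
      stop("ancestor_edge: edge {", s, ", ", t,
           "} connects a node to an ancestor/descendant")
    id <- if (is.null(sp$id) || is.na(sp$id)) {
      auto <- auto + 1L
      sprintf("%s--%s", s, t)
    } else as.character(sp$id)
    if (!is.null(g$edges[[id]])) stop("duplicate edge id: ", id)
    g$edges[[id]] <- cg_edge_record(id, s, t)
  }
  cg_update_compound_bounds(g)
}

cg_coerce_specs <- function(specs) {
  if (is.null(specs)) return(list())
  if (is.data.frame(specs)) {
    if (nrow(specs) == 0) return(list())
    return(lapply(seq_len(nrow(specs)), function(i) as.list(specs[i, , drop = FALSE])))
  }
  if (is.list(specs)) return(specs)
  stop("descriptors must be a data.frame or a list of lists")
}

cg_check_parent_acyclic <- function(graph) {
  for (id in names(graph$nodes)) {
    seen <- character()
    cur <- id
    while (!is.na(graph$nodes[[cur]]$parent)) {
      cur <- graph$nodes[[cur]]$parent
      if (cur %in% c(seen, id)) stop("not_a_tree: parent cycle involving ", id)
      if (is.null(graph$nodes[[cur]])) break
      seen <- c(seen, cur)
    }
  }
  invisible(TRUE)
}

## ---- structural lookups ---------------------------------------------------

cg_node <- function(graph, id) {
  nd <- graph$nodes[[as.character(id)]]
  if (is.null(nd)) stop("unknown node id: ", id)
  nd
}

cg_edge <- function(graph, id) {
  ed <- graph$edges[[as.character(id)]]
  if (is.null(ed)) stop("unknown edge id: ", id)
  ed
}

## parent -> character vector of child ids (active nodes only)
cg_children_map <- function(graph) {
  out <- list()
  for (nd in graph$nodes) {
    if (!is.na(nd$parent)) out[[nd$parent]] <- c(out[[nd$parent]], nd$id)
  }
  out
}

cg_ancestors <- function(graph, id) {
  out <- character()
  cur <- cg_node(graph, id)$parent
  while (!is.na(cur)) {
    out <- c(out, cur)
    nxt <- graph$nodes[[cur]]
    if (is.null(nxt)) break
    cur <- nxt$parent
  }
  out
}

cg_descendants <- function(graph, id, children = cg_children_map(graph)) {
  out <- character()
  queue <- children[[as.character(id)]]
  while (length(queue)) {
    out <- c(out, queue)
    queue <- unlist(lapply(queue, function(ch) children[[ch]]), use.names = FALSE)
  }
  out
}

cg_is_relative <- function(graph, a, b) {
  a %in% cg_ancestors(graph, b) || b %in% cg_ancestors(graph, a)
}

## TRUE when the node owns at least one active child, or is collapsed
cg_is_compound <- function(graph, id, children = cg_children_map(graph)) {
  nd <- cg_node(graph, id)
  nd$collapsed || length(children[[nd$id]]) > 0
}

cg_node_visible <- function(graph, id) {
  nd <- graph$nodes[[as.character(id)]]
  !is.null(nd) && !nd$hidden
}

cg_edge_visible <- function(graph, id) {
  ed <- graph$edges[[as.character(id)]]
  !is.null(ed) && !ed$hidden &&
    cg_node_visible(graph, ed$source) && cg_node_visible(graph, ed$target)
}

cg_visible_nodes <- function(graph) {
  ids <- names(graph$nodes)
  ids[vapply(ids, function(i) cg_node_visible(graph, i), logical(1))]
}

cg_visible_edges <- function(graph) {
  ids <- names(graph$edges)
  ids[vapply(ids, function(i) cg_edge_visible(graph, i), logical(1))]
}

## Lookup across active nodes plus every (nested) subgraph store.
cg_all_node_records <- function(graph) {
  out <- list()
  add <- function(nodes) {
    for (nd in nodes) {
      out[[nd$id]] <<- nd
      if (!is.null(nd$store)) add(nd$store$nodes)
    }
  }
  add(graph$nodes)
  out
}

cg_all_edge_records <- function(graph) {
  out <- list()
  for (ed in graph$edges) out[[ed$id]] <- ed
  add_store <- function(nodes) {
    for (nd in nodes) {
      if (!is.null(nd$store)) {
        for (ed in nd$store$edges) out[[ed$id]] <<- ed
        add_store(nd$store$nodes)
      }
    }
  }
  add_store(graph$nodes)
  out
}

## Representative of a (possibly archived) node: the node itself when active,
## otherwise the outermost active collapsed compound whose store contains it.
cg_representative <- function(graph, id, all_nodes = cg_all_node_records(graph)) {
  cur <- as.character(id)
  repeat {
    if (!is.null(graph$nodes[[cur]])) return(cur)
    rec <- all_nodes[[cur]]
    if (is.null(rec) || is.na(rec$parent))
      stop("cannot resolve representative for node: ", id)
    cur <- rec$parent
  }
}

## ---- queries --------------------------------------------------------------

#' Is an edge an inter-graph edge?
#'
#' An inter-graph edge connects nodes owned by different compound nodes (or
#' different owner graphs); equivalently, its endpoints have different
#' `parent` values.
#'
#' @param graph a `compound_graph`.
#' @param edge an active edge id.
#' @return `TRUE` iff the endpoints have different owners.
#' @export
is_inter_graph_edge <- function(graph, edge) {
  ed <- cg_edge(graph, edge)
  ps <- cg_node(graph, ed$source)$parent
  pt <- cg_node(graph, ed$target)$parent
  !identical(ps, pt) && !(is.na(ps) && is.na(pt))
}

#' Inclusion level of a node
#'
#' Number of ancestors on the path to the (virtual) root: nodes in the root
#' graph are at level 0.
#'
#' @inheritParams is_inter_graph_edge
#' @param node a node id.
#' @return a non-negative integer.
#' @export
inclusion_level <- function(graph, node) {
  length(cg_ancestors(graph, node))
}

#' Topmost container of a node within a compound
#'
#' For a compound `c` and a proper descendant `s` of `c`, returns the unique
#' child of `c` on the inclusion path from `c` down to `s` (which is `s`
#' itself when `s` is immediately contained in `c`).
#'
#' @inheritParams inclusion_level
#' @param c a compound node id.
#' @param s a node id that is a proper descendant of `c`.
#' @export
top_container_within <- function(graph, c, s) {
  c <- as.character(c); s <- as.character(s)
  cg_node(graph, c); cg_node(graph, s)
  chain <- c(s, cg_ancestors(graph, s))
  pos <- match(c, chain)
  if (is.na(pos) || pos == 1L)
    stop(s, " is not a proper descendant of ", c)
  chain[[pos - 1L]]
}

#' Visible neighbors within a shortest-path distance
#'
#' Breadth-first search from `node` over visible active edges (meta edges
#' included); hidden elements never contribute. The node itself is excluded.
#'
#' @inheritParams inclusion_level
#' @param k maximum shortest-path distance (positive integer).
#' @return a named integer vector mapping node id to distance, sorted by id.
#' @export
neighbors_within_distance <- function(graph, node, k) {
  node <- as.character(node)
  cg_node(graph, node)
  if (!cg_node_visible(graph, node)) stop("node is not visible: ", node)
  stopifnot(k >= 1)
  adj <- cg_visible_adjacency(graph)
  dist <- stats::setNames(0L, node)
  frontier <- node
  d <- 0L
  while (length(frontier) && d < k) {
    d <- d + 1L
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))
    if (length(nxt)) dist[nxt] <- d
    frontier <- nxt
  }
  out <- dist[setdiff(names(dist), node)]
  out[order(names(out))]
}

## visible adjacency as list: node id -> character vector of neighbor ids
cg_visible_adjacency <- function(graph) {
  adj <- list()
  for (id in cg_visible_edges(graph)) {
    ed <- graph$edges[[id]]
    adj[[ed$source]] <- c(adj[[ed$source]], ed$target)
    adj[[ed$target]] <- c(adj[[ed$target]], ed$source)
  }
  adj
}

## ---- validation -----------------------------------------------------------

cg_violation <- function(code, subject, message) {
  list(code = code, subject = as.character(subject), message = message)
}

#' Validate a compound graph
#'
#' Checks every structural invariant of the model: the inclusion relation is
#' a rooted tree; no adjacency edge connects a node to an ancestor or
#' descendant; geometry is positive and finite; meta edges resolve to exactly
#' one archived original each; collapsed state and stores agree. Violations
#' are returned (never raised), ordered by `(code, subject)`.
#'
#' @inheritParams is_inter_graph_edge
#' @return a list of violations, each with fields `code`, `subject`,
#'   `message`; empty iff the graph is valid.
#' @export
validate_graph <- function(graph) {
  v <- list()
  push <- function(code, subject, msg) v[[length(v) + 1L]] <<- cg_violation(code, subject, msg)

  for (nd in graph$nodes) {
    if (!is.na(nd$parent) && is.null(graph$nodes[[nd$parent]]))
      push("dangling_ref", nd$id, paste0("parent '", nd$parent, "' does not exist"))
    if (!is.finite(nd$x) || !is.finite(nd$y) ||
        !is.finite(nd$width) || !is.finite(nd$height) ||
        nd$width <= 0 || nd$height <= 0)
      push("bad_geometry", nd$id, "non-finite center or non-positive extent")
    if (nd$collapsed && is.null(nd$store))
      push("dangling_ref", nd$id, "collapsed node without a store")
    if (!nd$collapsed && !is.null(nd$store))
      push("dangling_ref", nd$id, "store present on a non-collapsed node")
    if (!is.null(nd$store)) {
      for (snd in nd$store$nodes) {
        if (!is.finite(snd$x) || !is.finite(snd$y))
          push("bad_geometry", snd$id, "non-finite relative position in store")
      }
    }
  }
  ## parent cycles among active nodes
  for (id in names(graph$nodes)) {
    seen <- id
    cur <- graph$nodes[[id]]$parent
    bad <- FALSE
    while (!is.na(cur) && !is.null(graph$nodes[[cur]])) {
      if (cur %in% seen) { bad <- TRUE; break }
      seen <- c(seen, cur)
      cur <- graph$nodes[[cur]]$parent
    }
    if (bad) push("not_a_tree", id, "parent chain contains a cycle")
  }
  for (ed in graph$edges) {
    miss <- FALSE
    for (endp in c(ed$source, ed$target)) {
      if (is.null(graph$nodes[[endp]])) {
        push("dangling_ref", ed$id, paste0("endpoint '", endp, "' does not exist"))
        miss <- TRUE
      }
    }
    if (miss) next
    if (identical(ed$source, ed$target)) {
      push("ancestor_edge", ed$id, "self loop")
    } else if (cg_tree_is_sane(graph) && cg_is_relative(graph, ed$source, ed$target)) {
      push("ancestor_edge", ed$id, "edge connects a node to an ancestor/descendant")
    }
    if (ed$kind == "meta") {
      if (is.na(ed$original_ref) ||
          is.null(graph$archived_originals[[ed$original_ref]]))
        push("meta_without_original", ed$id, "original_ref missing or unresolved")
    } else if (!is.na(ed$original_ref)) {
      push("meta_without_original", ed$id, "original edge carries an original_ref")
    }
  }
  ## each archived original must be referenced by exactly one meta edge,
  ## counting meta edges inside stores as well
  refs <- character()
  for (ed in cg_all_edge_records(graph)) {
    if (ed$kind == "meta" && !is.na(ed$original_ref)) refs <- c(refs, ed$original_ref)
  }
  cnt <- table(refs)
  for (oid in names(graph$archived_originals)) {
    n <- if (oid %in% names(cnt)) as.integer(cnt[[oid]]) else 0L
    if (n != 1L)
      push("meta_without_original", oid,
           sprintf("archived original referenced by %d meta edges (expected 1)", n))
  }
  ord <- order(vapply(v, `[[`, "", "code"), vapply(v, `[[`, "", "subject"))
  v[ord]
}

## cheap guard so ancestor walks terminate when the tree itself is broken
cg_tree_is_sane <- function(graph) {
  for (id in names(graph$nodes)) {
    seen <- id
    cur <- graph$nodes[[id]]$parent
    while (!is.na(cur)) {
      if (cur %in% seen || is.null(graph$nodes[[cur]])) return(FALSE)
      seen <- c(seen, cur)
      cur <- graph$nodes[[cur]]$parent
    }
  }
  TRUE
}

## ---- derived geometry -----------------------------------------------------

## Recompute bounds of every expanded compound bottom-up: bounding box of
## visible children plus a fixed margin on each side. Collapsed compounds and
## compounds with no visible children keep their geometry.
cg_update_compound_bounds <- function(graph) {
  children <- cg_children_map(graph)
  ids <- names(graph$nodes)
  if (!length(ids)) return(graph)
  depth <- vapply(ids, function(i) inclusion_level(graph, i), integer(1))
  for (id in ids[order(depth, decreasing = TRUE)]) {
    nd <- graph$nodes[[id]]
    if (nd$collapsed) next
    kids <- children[[id]]
    if (is.null(kids)) next
    vis <- kids[vapply(kids, function(k) cg_node_visible(graph, k), logical(1))]
    if (!length(vis)) next
    xs1 <- ys1 <- Inf; xs2 <- ys2 <- -Inf
    for (k in vis) {
      ch <- graph$nodes[[k]]
      xs1 <- min(xs1, ch$x - ch$width / 2);  xs2 <- max(xs2, ch$x + ch$width / 2)
      ys1 <- min(ys1, ch$y - ch$height / 2); ys2 <- max(ys2, ch$y + ch$height / 2)
    }
    nd$x <- (xs1 + xs2) / 2
    nd$y <- (ys1 + ys2) / 2
    nd$width <- (xs2 - xs1) + 2 * CG_COMPOUND_MARGIN
    nd$height <- (ys2 - ys1) + 2 * CG_COMPOUND_MARGIN
    graph$nodes[[id]] <- nd
  }
  graph
}

## ---- printing -------------------------------------------------------------

#' @export
print.compound_graph <- function(x, ...) {
  children <- cg_children_map(x)
  ncomp <- sum(vapply(names(x$nodes), function(i) cg_is_compound(x, i, children),
                      logical(1)))
  nmeta <- sum(vapply(x$edges, function(e) e$kind == "meta", logical(1)))
  cat(sprintf(
    "<compound_graph> %d nodes (%d compound), %d active edges (%d meta), %d archived originals\n",
    length(x$nodes), ncomp, length(x$edges), nmeta, length(x$archived_originals)))
  invisible(x)
}

#' Summary statistics of a compound graph
#'
#' @inheritParams is_inter_graph_edge
#' @return a list with counts of nodes, edges, meta edges, compounds,
#'   archived originals and the maximum nesting depth.
#' @export
graph_stats <- function(graph) {
  children <- cg_children_map(graph)
  ids <- names(graph$nodes)
  depth <- if (length(ids))
    max(vapply(ids, function(i) inclusion_level(graph, i), integer(1))) else 0L
  list(
    nodes = length(graph$nodes),
    edges = length(graph$edges),
    meta_edges = sum(vapply(graph$edges, function(e) e$kind == "meta", logical(1))),
    compounds = sum(vapply(ids, function(i) cg_is_compound(graph, i, children),
                           logical(1))),
    archived_originals = length(graph$archived_originals),
    max_depth = depth)
}
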