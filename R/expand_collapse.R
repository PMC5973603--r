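#' @title Expand and collapse of compound nodes
#' @description Collapse archives the (recursive) content of a compound node
#'   into its subgraph store and replaces every edge crossing the compound's
#'   boundary with a meta edge; expand restores the content and rewires or
#'   discards the incident meta edges. The bookkeeping is order independent:
#'   exactly one meta edge exists per archived original edge at all times, and
#'   the only extra memory a meta edge carries is a pointer to its original.
#' @name expand-collapse
NULL

cg_meta_id <- function(original_id) paste0("meta:", original_id)

cg_fire <- function(callback, graph, id) {
  if (is.function(callback)) callback(graph, id)
  invisible(NULL)
}

#' Collapse a compound node
#'
#' All descendants of `c` are moved into `c`'s subgraph store with positions
#' recorded relative to `c`'s centre (hidden flags preserved); edges lying
#' wholly inside move with them. Every edge with exactly one endpoint inside
#' `c` is replaced at the boundary: an original edge is archived and a meta
#' edge from `c` to the outside endpoint created (carrying a pointer to the
#' original), while an existing meta edge is simply reconnected to `c`,
#' keeping its pointer. The collapsed node takes fixed 30x30 extents at its
#' former centre. With `layout_after_op = "incremental"` a low-temperature
#' incremental layout then removes the space freed by the operation.
#'
#' @param graph a `compound_graph`.
#' @param c id of an expanded compound node with at least one child.
#' @param options a [cg_options()] list.
#' @return a list with the updated `graph` and an operation `report`.
#' @export
collapse_node <- function(graph, c, options = cg_options()) {
  c <- as.character(c)
  nd <- cg_node(graph, c)
  if (nd$collapsed) stop("node already collapsed: ", c)
  children <- cg_children_map(graph)
  if (!length(children[[c]])) stop("node is not a collapsible compound: ", c)

  cg_fire(options$before_collapse, graph, c)
  rep <- cg_report("collapse_node", c)
  desc <- cg_descendants(graph, c, children)
  inside <- stats::setNames(rep(TRUE, length(desc)), desc)
  store <- cg_empty_store()
  touches <- 0L

  for (eid in names(graph$edges)) {
    ed <- graph$edges[[eid]]
    s_in <- !is.na(inside[ed$source]); t_in <- !is.na(inside[ed$target])
    if (s_in && t_in) {
      store$edges[[eid]] <- ed
      graph$edges[[eid]] <- NULL
      rep$archived_elements <- c(rep$archived_elements, eid)
      touches <- touches + 1L
    } else if (s_in || t_in) {
      y <- if (s_in) ed$target else ed$source
      if (ed$kind == "original") {
        graph$archived_originals[[eid]] <- ed
        graph$edges[[eid]] <- NULL
        mid <- cg_meta_id(eid)
        graph$edges[[mid]] <- cg_edge_record(mid, c, y, kind = "meta",
                                             original_ref = eid,
                                             hidden = ed$hidden,
                                             highlighted = ed$highlighted)
        rep$created_meta_edges <- c(rep$created_meta_edges, mid)
        rep$archived_elements <- c(rep$archived_elements, eid)
        touches <- touches + 2L
      } else {
        old <- c(ed$source, ed$target)
        ed$source <- c; ed$target <- y
        graph$edges[[eid]] <- ed
        rep$reconnected_meta_edges[[length(rep$reconnected_meta_edges) + 1L]] <-
          list(id = eid, old = old, new = c(c, y))
        touches <- touches + 1L
      }
    }
  }

  cx <- nd$x; cy <- nd$y
  for (id in sort(desc)) {
    snd <- graph$nodes[[id]]
    snd$x <- snd$x - cx
    snd$y <- snd$y - cy
    store$nodes[[id]] <- snd
    graph$nodes[[id]] <- NULL
    rep$archived_elements <- c(rep$archived_elements, id)
  }
  nd$collapsed <- TRUE
  nd$store <- store
  nd$width <- CG_COLLAPSED_DIM
  nd$height <- CG_COLLAPSED_DIM
  graph$nodes[[c]] <- nd
  graph <- cg_update_compound_bounds(graph)

  if (identical(options$layout_after_op, "incremental")) {
    res <- cg_run_incremental(graph, options$layout)
    graph <- res$graph
    rep$layout_iterations <- res$iterations
  }
  rep$edge_touch_count <- touches
  cg_fire(options$after_collapse, graph, c)
  list(graph = graph, report = rep)
}

#' Expand a collapsed compound node
#'
#' The archived content is restored around the compound's *current* centre
#' (it may have been moved since the collapse), preserving the stored
#' sub-layout and hidden flags. Each meta edge incident to the compound is
#' then resolved against its original edge: when both original endpoints are
#' active again the meta edge is discarded and the original reactivated;
#' otherwise the meta edge is reconnected to the representative of each
#' endpoint (the outermost still-collapsed compound containing it), keeping
#' its pointer. With `options$fisheye` the surrounding nodes are first pushed
#' outward by the change in the node's required space, and with
#' `layout_after_op = "incremental"` a low-temperature polishing layout runs
#' afterwards.
#'
#' @inheritParams collapse_node
#' @param c id of a collapsed compound node.
#' @return a list with the updated `graph` and an operation `report`.
#' @export
expand_node <- function(graph, c, options = cg_options()) {
  c <- as.character(c)
  nd <- cg_node(graph, c)
  if (!nd$collapsed) stop("node is not collapsed: ", c)
  cg_fire(options$before_expand, graph, c)
  rep <- cg_report("expand_node", c)
  touches <- 0L
  store <- nd$store

  ## room-making: estimated extents of the restored content
  vis <- Filter(function(s) !s$hidden, store$nodes)
  if (length(vis) && isTRUE(options$fisheye)) {
    xs1 <- min(vapply(vis, function(s) s$x - s$width / 2, numeric(1)))
    xs2 <- max(vapply(vis, function(s) s$x + s$width / 2, numeric(1)))
    ys1 <- min(vapply(vis, function(s) s$y - s$height / 2, numeric(1)))
    ys2 <- max(vapply(vis, function(s) s$y + s$height / 2, numeric(1)))
    new_w <- (xs2 - xs1) + 2 * CG_COMPOUND_MARGIN
    new_h <- (ys2 - ys1) + 2 * CG_COMPOUND_MARGIN
    if (new_w > nd$width || new_h > nd$height)
      graph <- cg_fisheye_translate(graph, c, max(new_w, nd$width),
                                    max(new_h, nd$height))
    nd <- graph$nodes[[c]]
  }

  cx <- nd$x; cy <- nd$y
  for (id in sort(names(store$nodes))) {
    snd <- store$nodes[[id]]
    snd$x <- snd$x + cx
    snd$y <- snd$y + cy
    graph$nodes[[id]] <- snd
    rep$restored_elements <- c(rep$restored_elements, id)
  }
  for (eid in sort(names(store$edges))) {
    graph$edges[[eid]] <- store$edges[[eid]]
    rep$restored_elements <- c(rep$restored_elements, eid)
    touches <- touches + 1L
  }
  nd$collapsed <- FALSE
  nd["store"] <- list(NULL)
  graph$nodes[[c]] <- nd

  ## resolve meta edges incident to c against their originals
  metas <- Filter(function(e) e$kind == "meta" && (e$source == c || e$target == c),
                  graph$edges)
  all_nodes <- cg_all_node_records(graph)
  for (m in metas) {
    e <- graph$archived_originals[[m$original_ref]]
    rs <- cg_representative(graph, e$source, all_nodes)
    rt <- cg_representative(graph, e$target, all_nodes)
    if (identical(rs, e$source) && identical(rt, e$target)) {
      graph$edges[[m$id]] <- NULL
      graph$archived_originals[[e$id]] <- NULL
      graph$edges[[e$id]] <- e
      rep$discarded_meta_edges <- c(rep$discarded_meta_edges, m$id)
      rep$restored_elements <- c(rep$restored_elements, e$id)
      touches <- touches + 2L
    } else {
      old <- c(m$source, m$target)
      m$source <- rs; m$target <- rt
      graph$edges[[m$id]] <- m
      rep$reconnected_meta_edges[[length(rep$reconnected_meta_edges) + 1L]] <-
        list(id = m$id, old = old, new = c(rs, rt))
      touches <- touches + 1L
    }
  }
  graph <- cg_update_compound_bounds(graph)

  if (identical(options$layout_after_op, "incremental")) {
    res <- cg_run_incremental(graph, options$layout)
    graph <- res$graph
    rep$layout_iterations <- res$iterations
  }
  rep$edge_touch_count <- touches
  cg_fire(options$after_expand, graph, c)
  list(graph = graph, report = rep)
}

#' Collapse or expand a set of nodes
#'
#' `collapse_set()` collapses every collapsible member of `nodes` (and, with
#' `recursive = TRUE`, every compound nested inside them) in bottom-up
#' inclusion order, so that inner compounds are collapsed before outer ones.
#' `expand_set()` is the dual, working top-down and, when recursive,
#' following collapsed compounds revealed by each expansion.
#' Non-collapsible / non-expandable members are skipped and reported.
#' `collapse_all()` and `expand_all()` apply to the whole graph.
#'
#' @inheritParams collapse_node
#' @param nodes character vector of node ids.
#' @param recursive descend into nested compounds.
#' @return a list with the updated `graph` and a merged `report`.
#' @export
collapse_set <- function(graph, nodes, recursive = FALSE, options = cg_options()) {
  nodes <- unique(as.character(nodes))
  for (n in nodes) cg_node(graph, n)
  cand <- nodes
  if (recursive) {
    children <- cg_children_map(graph)
    cand <- unique(c(cand, unlist(lapply(nodes, function(n)
      cg_descendants(graph, n, children)), use.names = FALSE)))
  }
  lev <- vapply(cand, function(n) inclusion_level(graph, n), integer(1))
  cand <- cand[order(-lev, cand)]
  reports <- list()
  skipped <- character()
  for (n in cand) {
    st <- if (is.null(graph$nodes[[n]])) list(collapsible = FALSE)
          else node_op_state(graph, n)
    if (isTRUE(st$collapsible)) {
      res <- collapse_node(graph, n, options)
      graph <- res$graph
      reports[[length(reports) + 1L]] <- res$report
    } else skipped <- c(skipped, n)
  }
  rep <- cg_merge_reports("collapse_set", nodes, reports)
  rep$skipped <- skipped
  list(graph = graph, report = rep)
}

#' @rdname collapse_set
#' @export
expand_set <- function(graph, nodes, recursive = FALSE, options = cg_options()) {
  nodes <- unique(as.character(nodes))
  for (n in nodes) cg_node(graph, n)
  lev <- vapply(nodes, function(n) inclusion_level(graph, n), integer(1))
  queue <- nodes[order(lev, nodes)]
  reports <- list()
  skipped <- character()
  while (length(queue)) {
    n <- queue[[1]]; queue <- queue[-1]
    nd <- graph$nodes[[n]]
    if (!is.null(nd) && nd$collapsed) {
      res <- expand_node(graph, n, options)
      graph <- res$graph
      reports[[length(reports) + 1L]] <- res$report
      if (recursive) {
        revealed <- Filter(function(id) {
          r <- graph$nodes[[id]]
          !is.null(r) && r$collapsed
        }, res$report$restored_elements)
        queue <- c(queue, unlist(revealed, use.names = FALSE))
      }
    } else skipped <- c(skipped, n)
  }
  rep <- cg_merge_reports("expand_set", nodes, reports)
  rep$skipped <- skipped
  list(graph = graph, report = rep)
}

#' @rdname collapse_set
#' @export
collapse_all <- function(graph, options = cg_options()) {
  res <- collapse_set(graph, names(graph$nodes), recursive = TRUE, options = options)
  res$report$operation <- "collapse_all"
  res
}

#' @rdname collapse_set
#' @export
expand_all <- function(graph, options = cg_options()) {
  res <- expand_set(graph, names(graph$nodes), recursive = TRUE, options = options)
  res$report$operation <- "expand_all"
  res
}

#' Expand/collapse state of a node
#'
#' A node is expandable iff it is collapsed, and collapsible iff it is an
#' expanded compound with at least one child.
#'
#' @inheritParams collapse_node
#' @param node a node id.
#' @return list with logical fields `collapsible` and `expandable`.
#' @export
node_op_state <- function(graph, node) {
  nd <- cg_node(graph, node)
  children <- cg_children_map(graph)
  list(collapsible = !nd$collapsed && length(children[[nd$id]]) > 0,
       expandable = nd$collapsed)
}

#' @rdname node_op_state
#' @param nodes character vector of node ids to filter.
#' @export
collapsible_nodes <- function(graph, nodes = names(graph$nodes)) {
  nodes[vapply(nodes, function(n) node_op_state(graph, n)$collapsible, logical(1))]
}

#' @rdname node_op_state
#' @export
expandable_nodes <- function(graph, nodes = names(graph$nodes)) {
  nodes[vapply(nodes, function(n) node_op_state(graph, n)$expandable, logical(1))]
}

#' Content archived under collapsed compounds
#'
#' `mode = "direct"` returns the immediate content of `node`'s store;
#' `"recursive"` also descends the stores of nested collapsed compounds;
#' `"all_graph"` unions the recursive content of every active collapsed
#' compound (ignoring `node`). Inter-graph originals currently represented
#' by meta edges live in the graph-level archive, not in any store, and are
#' therefore not part of the result.
#'
#' @inheritParams node_op_state
#' @param mode one of `"direct"`, `"recursive"`, `"all_graph"`.
#' @return list with sorted character vectors `nodes` and `edges`.
#' @export
collapsed_children <- function(graph, node = NULL,
                               mode = c("direct", "recursive", "all_graph")) {
  mode <- match.arg(mode)
  collect <- function(store, recurse) {
    ## meta edges parked in a store are bookkeeping, not archived content
    orig <- Filter(function(e) e$kind == "original", store$edges)
    out <- list(nodes = names(store$nodes), edges = names(orig))
    if (recurse) {
      for (snd in store$nodes) {
        if (!is.null(snd$store)) {
          sub <- collect(snd$store, TRUE)
          out$nodes <- c(out$nodes, sub$nodes)
          out$edges <- c(out$edges, sub$edges)
        }
      }
    }
    out
  }
  if (mode == "all_graph") {
    out <- list(nodes = character(), edges = character())
    for (nd in graph$nodes) {
      if (nd$collapsed) {
        sub <- collect(nd$store, TRUE)
        out$nodes <- c(out$nodes, sub$nodes)
        out$edges <- c(out$edges, sub$edges)
      }
    }
  } else {
    nd <- cg_node(graph, node)
    if (!nd$collapsed) stop("node is not collapsed: ", node)
    out <- collect(nd$store, mode == "recursive")
  }
  list(nodes = sort(unique(as.character(out$nodes))),
       edges = sort(unique(as.character(out$edges))))
}
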