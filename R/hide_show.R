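#' @title Hide and show with heuristic re-placement
#' @description Hiding removes elements from the visible drawing (they keep
#'   their coordinates and archived state); showing re-introduces them level
#'   by level, placing each newly revealed neighbor roughly one ideal edge
#'   length from its visible anchor inside the anchor's least crowded
#'   quadrant, and interleaving a fixed number of incremental layout
#'   iterations between levels so the drawing absorbs each wave of nodes
#'   before the next arrives.
#' @name hide-show
NULL

CG_QUADRANTS <- c("I", "II", "III", "IV")
CG_QUADRANT_BISECTOR <- c(I = 45, II = 135, III = 225, IV = 315)
CG_SCORE_FIRST_DEGREE <- 3L
CG_SCORE_SECOND_DEGREE <- 1L

## axis-aligned quadrant of a point relative to an anchor, in y-up model
## space; boundary points count toward the lower-numbered adjacent quadrant
cg_quadrant_of <- function(dx, dy) {
  if (dx >= 0 && dy >= 0) "I"
  else if (dx < 0 && dy >= 0) "II"
  else if (dx <= 0 && dy < 0) "III"
  else "IV"
}

cg_element_exists <- function(graph, id) {
  !is.null(graph$nodes[[id]]) || !is.null(graph$edges[[id]])
}

#' Hide elements
#'
#' Listed nodes become hidden together with every edge incident to them
#' (edge visibility is derived: an edge is visible only while both endpoints
#' are); explicitly listed edges are flagged hidden on their own. Hidden
#' elements keep their coordinates. With
#' `options$layout_after_op = "incremental"` a low-temperature incremental
#' layout then tightens the visible remainder.
#'
#' @inheritParams collapse_node
#' @param elements character vector of node and/or edge ids.
#' @return a list with the updated `graph` and a `report` whose
#'   `hidden_elements` lists every newly invisible element (including edges
#'   hidden implicitly).
#' @export
hide_elements <- function(graph, elements, options = cg_options()) {
  elements <- unique(as.character(elements))
  for (id in elements) {
    if (!cg_element_exists(graph, id)) stop("unknown element id: ", id)
  }
  before <- c(cg_visible_nodes(graph), cg_visible_edges(graph))
  for (id in elements) {
    if (!is.null(graph$nodes[[id]])) graph$nodes[[id]]$hidden <- TRUE
    else graph$edges[[id]]$hidden <- TRUE
  }
  graph <- cg_update_compound_bounds(graph)
  after <- c(cg_visible_nodes(graph), cg_visible_edges(graph))
  rep <- cg_report("hide", elements, hidden_elements = sort(setdiff(before, after)))
  if (identical(options$layout_after_op, "incremental") && length(elements)) {
    res <- cg_run_incremental(graph, options$layout)
    graph <- res$graph
    rep$layout_iterations <- res$iterations
  }
  list(graph = graph, report = rep)
}

#' Quadrant crowding scores around a node
#'
#' The space around the anchor is split into the four axis-aligned quadrants
#' (y-up model space; I = +x+y, II = -x+y, III = -x-y, IV = +x-y). Every
#' visible node at shortest-path distance 1 from the anchor adds +3 to the
#' quadrant containing its centre and every node at distance 2 adds +1; the
#' least crowded quadrant is chosen for placing newly revealed neighbors,
#' with ties broken in the order I < II < III < IV. Nodes exactly on a
#' quadrant boundary count toward the lower-numbered adjacent quadrant.
#'
#' @inheritParams collapse_node
#' @param anchor id of a visible node.
#' @return a list of class `cg_quadrant_scores` with integer `scores` (named
#'   I..IV), the `chosen` quadrant, and the two score constants.
#' @export
quadrant_scores <- function(graph, anchor) {
  anchor <- as.character(anchor)
  nd <- cg_node(graph, anchor)
  if (!cg_node_visible(graph, anchor)) stop("anchor is hidden: ", anchor)
  scores <- stats::setNames(integer(4), CG_QUADRANTS)
  nb <- neighbors_within_distance(graph, anchor, 2L)
  for (id in names(nb)) {
    b <- graph$nodes[[id]]
    q <- cg_quadrant_of(b$x - nd$x, b$y - nd$y)
    scores[q] <- scores[q] +
      if (nb[[id]] == 1L) CG_SCORE_FIRST_DEGREE else CG_SCORE_SECOND_DEGREE
  }
  structure(list(scores = scores,
                 chosen = CG_QUADRANTS[which.min(scores)],
                 score_first_degree = CG_SCORE_FIRST_DEGREE,
                 score_second_degree = CG_SCORE_SECOND_DEGREE),
            class = "cg_quadrant_scores")
}

#' @export
print.cg_quadrant_scores <- function(x, ...) {
  cat("<quadrant scores>",
      paste(sprintf("%s=%d", names(x$scores), x$scores), collapse = " "),
      "chosen:", x$chosen, "\n")
  invisible(x)
}

#' Place newly revealed neighbors of an anchor
#'
#' Each node receives a centre at a distance `l * (1 +/- radial_jitter)`
#' from the anchor, at an angle drawn uniformly within `angular_jitter`
#' degrees of the chosen (least crowded) quadrant's bisector. Draws consume
#' a generator seeded with `params$seed`, in sorted-id order, so placement
#' is reproducible.
#'
#' @inheritParams quadrant_scores
#' @param new_nodes ids of hidden neighbors of `anchor` being revealed.
#' @param params a [placement_params()] list.
#' @return a numeric matrix of centres (rownames = node ids, columns x, y).
#' @export
place_unhidden_level <- function(graph, anchor, new_nodes,
                                 params = placement_params()) {
  cg_with_seed(params$seed,
               cg_place_level(graph, anchor, new_nodes, params))
}

## draws from the current RNG stream
cg_place_level <- function(graph, anchor, new_nodes, params) {
  anchor <- as.character(anchor)
  nd <- cg_node(graph, anchor)
  if (!cg_node_visible(graph, anchor)) stop("anchor is hidden: ", anchor)
  new_nodes <- sort(unique(as.character(new_nodes)))
  out <- matrix(numeric(0), nrow = 0, ncol = 2,
                dimnames = list(NULL, c("x", "y")))
  if (!length(new_nodes)) return(out)
  for (id in new_nodes) {
    adj <- any(vapply(graph$edges, function(e)
      (e$source == anchor && e$target == id) ||
        (e$target == anchor && e$source == id), logical(1)))
    if (!adj) stop("node ", id, " is not adjacent to anchor ", anchor)
  }
  chosen <- quadrant_scores(graph, anchor)$chosen
  bis <- CG_QUADRANT_BISECTOR[[chosen]]
  out <- matrix(0, nrow = length(new_nodes), ncol = 2,
                dimnames = list(new_nodes, c("x", "y")))
  for (id in new_nodes) {
    r <- params$ideal_edge_length *
      (1 + stats::runif(1, -params$radial_jitter, params$radial_jitter))
    ang <- (bis + stats::runif(1, -params$angular_jitter,
                               params$angular_jitter)) * pi / 180
    out[id, ] <- c(nd$x + r * cos(ang), nd$y + r * sin(ang))
  }
  out
}

#' Show (unhide) elements
#'
#' Listed edges are unflagged directly. Listed nodes are partitioned into
#' levels by shortest-path distance, over the edges being revealed, to the
#' nearest currently visible node. Levels are introduced one at a time: each
#' node picks as anchor its smallest-id visible neighbor, the anchor's least
#' crowded quadrant is computed, the node is placed roughly one ideal edge
#' length into that quadrant, and after each level `iterations_per_level`
#' incremental layout iterations run before the next level is placed, so
#' layout adjustment interleaves with the reveal. Nodes with no path to a
#' visible anchor reappear at their stored coordinates. Edges become visible
#' as soon as both endpoints are.
#'
#' @inheritParams hide_elements
#' @param params a [placement_params()] list.
#' @return a list with the updated `graph` and a `report` carrying the level
#'   structure (`levels`) and all newly visible ids (`shown_elements`).
#' @export
show_elements <- function(graph, elements, options = cg_options(),
                          params = placement_params()) {
  elements <- unique(as.character(elements))
  for (id in elements) {
    if (!cg_element_exists(graph, id)) stop("unknown element id: ", id)
  }
  before <- c(cg_visible_nodes(graph), cg_visible_edges(graph))
  node_set <- elements[vapply(elements, function(i) !is.null(graph$nodes[[i]]),
                              logical(1))]
  edge_set <- setdiff(elements, node_set)
  for (id in edge_set) graph$edges[[id]]$hidden <- FALSE
  node_set <- node_set[vapply(node_set, function(i) graph$nodes[[i]]$hidden,
                              logical(1))]

  ## final visibility of an edge once all of node_set is shown
  vis_after_nodes <- union(cg_visible_nodes(graph), node_set)
  revealed_adj <- list()
  for (ed in graph$edges) {
    if (!ed$hidden && ed$source %in% vis_after_nodes &&
        ed$target %in% vis_after_nodes) {
      revealed_adj[[ed$source]] <- c(revealed_adj[[ed$source]], ed$target)
      revealed_adj[[ed$target]] <- c(revealed_adj[[ed$target]], ed$source)
    }
  }
  ## BFS levels from the currently visible frontier
  lvl <- stats::setNames(rep(NA_integer_, length(node_set)), node_set)
  frontier <- cg_visible_nodes(graph)
  d <- 0L
  seen <- frontier
  while (length(frontier) && anyNA(lvl)) {
    d <- d + 1L
    nxt <- setdiff(unique(unlist(revealed_adj[frontier], use.names = FALSE)), seen)
    hit <- intersect(nxt, node_set)
    if (length(hit)) lvl[hit] <- d
    seen <- c(seen, nxt)
    frontier <- nxt
  }

  rep <- cg_report("show", elements)
  detached <- names(lvl)[is.na(lvl)]
  for (id in detached) graph$nodes[[id]]$hidden <- FALSE
  if (length(detached))
    rep$levels[["detached"]] <- sort(detached)

  total_iter <- 0L
  graph <- cg_with_seed(params$seed, {
    for (d in sort(unique(lvl[!is.na(lvl)]))) {
      members <- sort(names(lvl)[!is.na(lvl) & lvl == d])
      ## anchor per node: smallest-id visible neighbor (revealed topology)
      anchors <- vapply(members, function(id) {
        nb <- revealed_adj[[id]]
        vis <- nb[vapply(nb, function(x) cg_node_visible(graph, x), logical(1))]
        if (!length(vis)) NA_character_ else min(vis)
      }, character(1))
      for (a in sort(unique(stats::na.omit(anchors)))) {
        grp <- members[!is.na(anchors) & anchors == a]
        pos <- cg_place_level(graph, a, grp, params)
        for (id in grp) {
          nd <- graph$nodes[[id]]
          nd$x <- pos[id, "x"]; nd$y <- pos[id, "y"]; nd$hidden <- FALSE
          graph$nodes[[id]] <- nd
          rep$placements[[id]] <- list(
            anchor = a, x = pos[id, "x"], y = pos[id, "y"],
            anchor_x = graph$nodes[[a]]$x, anchor_y = graph$nodes[[a]]$y)
        }
      }
      ## a node whose anchors are all still hidden (same-level cluster):
      ## reveal at stored coordinates
      for (id in members[is.na(anchors)]) graph$nodes[[id]]$hidden <- FALSE
      graph <- cg_update_compound_bounds(graph)
      rep$levels[[as.character(d)]] <- members
      res <- cg_run_incremental(graph, options$layout,
                                exact_iterations = params$iterations_per_level)
      graph <- res$graph
      total_iter <- total_iter + res$iterations
    }
    graph
  })
  graph <- cg_update_compound_bounds(graph)
  after <- c(cg_visible_nodes(graph), cg_visible_edges(graph))
  rep$shown_elements <- sort(setdiff(after, before))
  rep$layout_iterations <- total_iter
  list(graph = graph, report = rep)
}

#' Manage highlight state
#'
#' The first highlighting call activates highlight mode, implicitly marking
#' every non-listed element unhighlighted (renderers then draw them at the
#' configured reduced opacity). Neighbor modes extend the listed set with
#' adjacent visible nodes and incident visible edges; `remove_all` clears
#' every flag and leaves highlight mode.
#'
#' @inheritParams hide_elements
#' @param mode one of `"highlight"`, `"unhighlight"`,
#'   `"highlight_neighbors"`, `"unhighlight_neighbors"`, `"remove_all"`.
#' @param neighbor_provider optional `function(graph, node_id)` returning the
#'   neighbor node ids used by the neighbor modes (defaults to visible
#'   adjacency).
#' @return a list with the updated `graph` and a `report`.
#' @export
set_highlight <- function(graph, elements = character(),
                          mode = c("highlight", "unhighlight",
                                   "highlight_neighbors",
                                   "unhighlight_neighbors", "remove_all"),
                          neighbor_provider = NULL) {
  mode <- match.arg(mode)
  elements <- unique(as.character(elements))
  for (id in elements) {
    if (!cg_element_exists(graph, id)) stop("unknown element id: ", id)
  }
  if (mode == "remove_all") {
    for (id in names(graph$nodes)) graph$nodes[[id]]$highlighted <- FALSE
    for (id in names(graph$edges)) graph$edges[[id]]$highlighted <- FALSE
    graph$highlight_active <- FALSE
    return(list(graph = graph,
                report = cg_report("set_highlight", "remove_all")))
  }
  if (mode %in% c("highlight_neighbors", "unhighlight_neighbors")) {
    extra <- character()
    for (id in intersect(elements, names(graph$nodes))) {
      nb <- if (is.function(neighbor_provider)) neighbor_provider(graph, id)
            else {
              adj <- cg_visible_adjacency(graph)
              unique(adj[[id]])
            }
      extra <- c(extra, nb)
      for (eid in cg_visible_edges(graph)) {
        ed <- graph$edges[[eid]]
        if (ed$source == id || ed$target == id) extra <- c(extra, eid)
      }
    }
    elements <- unique(c(elements, extra))
    mode <- sub("_neighbors", "", mode)
  }
  flag <- identical(mode, "highlight")
  if (flag && !graph$highlight_active) graph$highlight_active <- TRUE
  for (id in elements) {
    if (!is.null(graph$nodes[[id]])) graph$nodes[[id]]$highlighted <- flag
    else graph$edges[[id]]$highlighted <- flag
  }
  list(graph = graph,
       report = cg_report("set_highlight", elements))
}
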