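#' @title Force-directed layout with compound support
#' @description A spring-embedder over the visible part of a compound graph.
#'   Visible leaf nodes (including collapsed compounds) are the moving
#'   particles; expanded compound bounds are derived from their children every
#'   iteration. Springs act along visible edges with a rest length that grows
#'   with the nesting-level difference of the endpoints, all particle pairs
#'   repel with an inverse-square force over their box-boundary distance, and
#'   a weak constant gravity pulls particles toward their owning compound's
#'   centre. A simulated-annealing temperature caps the per-iteration
#'   displacement: static runs start hot, incremental runs (which begin from
#'   the current coordinates) start at a low temperature so the mental map of
#'   the drawing is preserved.
#' @name layout
NULL

## Visible leaf particles: visible nodes without visible children
## (collapsed compounds are leaves from the layout's point of view).
cg_particles <- function(graph) {
  children <- cg_children_map(graph)
  vis <- cg_visible_nodes(graph)
  vis[vapply(vis, function(id) {
    nd <- graph$nodes[[id]]
    if (nd$collapsed) return(TRUE)
    kids <- children[[id]]
    !any(vapply(kids, function(k) cg_node_visible(graph, k), logical(1)))
  }, logical(1))]
}

## leaf particles representing a node for spring forces
cg_particle_set <- function(graph, id, particles, children) {
  if (id %in% particles) return(id)
  desc <- cg_descendants(graph, id, children)
  intersect(desc, particles)
}

cg_box_distance <- function(a, b) {
  dx <- max(0, abs(a$x - b$x) - (a$width + b$width) / 2)
  dy <- max(0, abs(a$y - b$y) - (a$height + b$height) / 2)
  max(1, sqrt(dx * dx + dy * dy))
}

## one force iteration; returns list(graph, mean_disp)
cg_layout_step <- function(graph, params, temperature) {
  particles <- cg_particles(graph)
  np <- length(particles)
  if (np == 0L) return(list(graph = graph, mean_disp = 0))
  children <- cg_children_map(graph)
  fx <- stats::setNames(numeric(np), particles)
  fy <- fx

  ## springs along visible edges
  for (eid in cg_visible_edges(graph)) {
    ed <- graph$edges[[eid]]
    a <- graph$nodes[[ed$source]]; b <- graph$nodes[[ed$target]]
    dx <- b$x - a$x; dy <- b$y - a$y
    d <- sqrt(dx * dx + dy * dy)
    if (d < 1e-9) next
    lev <- abs(inclusion_level(graph, ed$source) - inclusion_level(graph, ed$target))
    le <- params$ideal_edge_length * (1 + params$nesting_length_factor * lev)
    f <- params$spring_constant * (d - le)
    ux <- dx / d; uy <- dy / d
    pa <- cg_particle_set(graph, ed$source, particles, children)
    pb <- cg_particle_set(graph, ed$target, particles, children)
    if (length(pa)) {
      fx[pa] <- fx[pa] + f * ux / length(pa)
      fy[pa] <- fy[pa] + f * uy / length(pa)
    }
    if (length(pb)) {
      fx[pb] <- fx[pb] - f * ux / length(pb)
      fy[pb] <- fy[pb] - f * uy / length(pb)
    }
  }

  ## pairwise repulsion between particles
  if (np > 1L) {
    for (i in seq_len(np - 1L)) {
      a <- graph$nodes[[particles[i]]]
      for (j in seq.int(i + 1L, np)) {
        b <- graph$nodes[[particles[j]]]
        dx <- b$x - a$x; dy <- b$y - a$y
        d <- sqrt(dx * dx + dy * dy)
        if (d < 1e-9) {
          ang <- 2 * pi * (i * np + j) / (np * np + 1)
          ux <- cos(ang); uy <- sin(ang)
        } else {
          ux <- dx / d; uy <- dy / d
        }
        f <- params$repulsion_constant / cg_box_distance(a, b)^2
        fx[i] <- fx[i] - f * ux; fy[i] <- fy[i] - f * uy
        fx[j] <- fx[j] + f * ux; fy[j] <- fy[j] + f * uy
      }
    }
  }

  ## gravity toward the owning compound's centre (root particles gravitate
  ## toward the centroid of the root-level visible nodes)
  if (params$gravity_constant > 0) {
    roots <- Filter(function(id) is.na(graph$nodes[[id]]$parent),
                    cg_visible_nodes(graph))
    gx0 <- mean(vapply(roots, function(id) graph$nodes[[id]]$x, numeric(1)))
    gy0 <- mean(vapply(roots, function(id) graph$nodes[[id]]$y, numeric(1)))
    for (i in seq_len(np)) {
      nd <- graph$nodes[[particles[i]]]
      if (is.na(nd$parent)) { tx <- gx0; ty <- gy0 }
      else { p <- graph$nodes[[nd$parent]]; tx <- p$x; ty <- p$y }
      dx <- tx - nd$x; dy <- ty - nd$y
      d <- sqrt(dx * dx + dy * dy)
      if (d > 1e-9) {
        fx[i] <- fx[i] + params$gravity_constant * dx / d
        fy[i] <- fy[i] + params$gravity_constant * dy / d
      }
    }
  }

  ## displacement capped at the temperature
  total <- 0
  for (i in seq_len(np)) {
    mag <- sqrt(fx[i]^2 + fy[i]^2)
    if (mag > temperature && mag > 0) {
      fx[i] <- fx[i] * temperature / mag
      fy[i] <- fy[i] * temperature / mag
      mag <- temperature
    }
    nd <- graph$nodes[[particles[i]]]
    nd$x <- nd$x + fx[i]; nd$y <- nd$y + fy[i]
    graph$nodes[[particles[i]]] <- nd
    total <- total + mag
  }
  graph <- cg_update_compound_bounds(graph)
  list(graph = graph, mean_disp = total / np)
}

#' Run a force-directed layout
#'
#' Static mode (`params$incremental = FALSE`) first places the particles
#' uniformly at random (seeded) in a square of side `l * sqrt(n)`;
#' incremental mode starts from the current (finite) coordinates and a low
#' initial temperature. The run stops at `max_iterations` or when the mean
#' displacement of an iteration falls below `convergence_threshold`.
#'
#' @inheritParams collapse_node
#' @param params a [layout_params()] list.
#' @return a numeric matrix of final centres (rownames = visible node ids,
#'   columns `x`, `y`) with attribute `"iterations"`; apply it with
#'   [apply_layout()].
#' @export
force_layout <- function(graph, params = layout_params()) {
  res <- cg_force_layout_run(graph, params)
  pos <- cg_positions(res$graph)
  attr(pos, "iterations") <- res$iterations
  pos
}

cg_positions <- function(graph) {
  ids <- sort(cg_visible_nodes(graph))
  m <- matrix(0, nrow = length(ids), ncol = 2,
              dimnames = list(ids, c("x", "y")))
  for (id in ids) m[id, ] <- c(graph$nodes[[id]]$x, graph$nodes[[id]]$y)
  m
}

cg_force_layout_run <- function(graph, params, exact_iterations = NULL) {
  particles <- cg_particles(graph)
  if (!length(particles)) return(list(graph = graph, iterations = 0L))
  if (!params$incremental) {
    side <- params$ideal_edge_length * sqrt(length(particles))
    graph <- cg_with_seed(params$seed, {
      for (id in sort(particles)) {
        nd <- graph$nodes[[id]]
        nd$x <- stats::runif(1, -side / 2, side / 2)
        nd$y <- stats::runif(1, -side / 2, side / 2)
        graph$nodes[[id]] <- nd
      }
      graph
    })
    graph <- cg_update_compound_bounds(graph)
    t0 <- params$initial_temperature_static
  } else {
    for (id in particles) {
      nd <- graph$nodes[[id]]
      if (!is.finite(nd$x) || !is.finite(nd$y))
        stop("incremental layout requires finite coordinates (node ", id, ")")
    }
    t0 <- params$initial_temperature_incremental
  }
  niter <- if (is.null(exact_iterations)) params$max_iterations
           else as.integer(exact_iterations)
  done <- 0L
  for (i in seq_len(niter)) {
    temp <- t0 * params$cooling_factor^(i - 1L)
    st <- cg_layout_step(graph, params, temp)
    graph <- st$graph
    done <- i
    if (is.null(exact_iterations) && st$mean_disp < params$convergence_threshold)
      break
  }
  list(graph = graph, iterations = done)
}

## incremental polishing run used as the post-operation layout hook
cg_run_incremental <- function(graph, params, exact_iterations = NULL) {
  p <- params
  p$incremental <- TRUE
  res <- cg_force_layout_run(graph, p, exact_iterations)
  list(graph = res$graph, iterations = res$iterations)
}

#' Apply a position map to a graph
#'
#' Sets the centres of the listed nodes and recomputes derived compound
#' bounds. Positions of expanded compounds are ignored (their geometry is
#' always derived from their children).
#'
#' @inheritParams collapse_node
#' @param positions a numeric matrix with rownames naming nodes and columns
#'   `x`, `y`, as returned by [force_layout()] or [fisheye_adjust()].
#' @return the updated `compound_graph`.
#' @export
apply_layout <- function(graph, positions) {
  for (id in rownames(positions)) {
    nd <- graph$nodes[[id]]
    if (is.null(nd)) next
    nd$x <- positions[id, "x"]; nd$y <- positions[id, "y"]
    graph$nodes[[id]] <- nd
  }
  cg_update_compound_bounds(graph)
}

#' Energy of the current drawing
#'
#' Sum over visible edges of the spring potential
#' `0.5 * spring_constant * (d - l_e)^2` plus, over every repelling particle
#' pair, `repulsion_constant / d` (with `d` the clamped box-boundary
#' distance). Lower is better; incremental layouts should not increase it.
#'
#' @inheritParams force_layout
#' @return a non-negative number.
#' @export
drawing_energy <- function(graph, params = layout_params()) {
  e <- 0
  for (eid in cg_visible_edges(graph)) {
    ed <- graph$edges[[eid]]
    a <- graph$nodes[[ed$source]]; b <- graph$nodes[[ed$target]]
    d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2)
    lev <- abs(inclusion_level(graph, ed$source) - inclusion_level(graph, ed$target))
    le <- params$ideal_edge_length * (1 + params$nesting_length_factor * lev)
    e <- e + 0.5 * params$spring_constant * (d - le)^2
  }
  particles <- cg_particles(graph)
  np <- length(particles)
  if (np > 1L) {
    for (i in seq_len(np - 1L)) {
      for (j in seq.int(i + 1L, np)) {
        e <- e + params$repulsion_constant /
          cg_box_distance(graph$nodes[[particles[i]]], graph$nodes[[particles[j]]])
      }
    }
  }
  e
}

## ---- fisheye space adjustment --------------------------------------------

#' Fisheye space adjustment around a resizing node
#'
#' When a node grows from its current extents to `new_width` x `new_height`
#' (keeping its centre), the surrounding nodes must be pushed outward to make
#' room, by as much as the change in the required space
#' `(T_x, T_y) = ((new_width - old_width)/2, (new_height - old_height)/2)`.
#' Every visible node that is neither the anchor nor one of its ancestors or
#' descendants translates by `T_x` away from the anchor's vertical axis and
#' by `T_y` away from its horizontal axis (components on an axis do not
#' move), so purely horizontal neighbors move by exactly `T_x`, purely
#' vertical ones by exactly `T_y`, the sign of every relative coordinate is
#' preserved, and shrinking back to the original extents is the exact
#' inverse. Ancestor compound bounds are recomputed afterwards.
#'
#' @inheritParams collapse_node
#' @param anchor id of the visible node changing size.
#' @param new_width,new_height the anchor's new extents (positive units).
#' @return a list with the updated `graph` and a `positions` matrix of the
#'   visible node centres after the adjustment.
#' @export
fisheye_adjust <- function(graph, anchor, new_width, new_height) {
  graph <- cg_fisheye_translate(graph, anchor, new_width, new_height)
  list(graph = graph, positions = cg_positions(graph))
}

cg_fisheye_translate <- function(graph, anchor, new_width, new_height) {
  anchor <- as.character(anchor)
  nd <- cg_node(graph, anchor)
  if (nd$hidden) stop("anchor is hidden: ", anchor)
  stopifnot(new_width > 0, new_height > 0)
  tx <- (new_width - nd$width) / 2
  ty <- (new_height - nd$height) / 2
  excluded <- c(anchor, cg_ancestors(graph, anchor),
                cg_descendants(graph, anchor))
  for (id in cg_visible_nodes(graph)) {
    if (id %in% excluded) next
    b <- graph$nodes[[id]]
    dx <- b$x - nd$x; dy <- b$y - nd$y
    if (dx > 0) b$x <- nd$x + max(dx + tx, 0)
    else if (dx < 0) b$x <- nd$x + min(dx - tx, 0)
    if (dy > 0) b$y <- nd$y + max(dy + ty, 0)
    else if (dy < 0) b$y <- nd$y + min(dy - ty, 0)
    graph$nodes[[id]] <- b
  }
  nd$width <- new_width; nd$height <- new_height
  graph$nodes[[anchor]] <- nd
  cg_update_compound_bounds(graph)
}
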