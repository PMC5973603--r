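#' @title Synthetic compound graphs
#' @description Deterministic fixtures and seeded random generators so every
#'   operation can be exercised without external data: a six-node worked
#'   example with two nested compounds, a seeded random nested-graph
#'   generator with controllable nesting depth, edge density and inter-graph
#'   edge probability, and a plain lattice used by the fisheye tests.
#' @name fixtures
NULL

#' Six-node worked example with two nested compounds
#'
#' Nodes `a`, `b`, `c1`, `c2`, `d`, `e` where compound `c1` (root level)
#' contains `a`, `b`, `c2` and `d`, and compound `c2` contains `e`; edges
#' `{a,b}`, `{b,d}` and `{d,e}`, of which only `{d,e}` is an inter-graph
#' edge. Geometry is fixed so the fixture is fully deterministic.
#'
#' @return a valid `compound_graph` with 6 nodes, 3 edges and 2 compounds.
#' @examples
#' g <- example_compound_graph()
#' graph_stats(g)
#' @export
example_compound_graph <- function() {
  nodes <- data.frame(
    id     = c("c1", "a", "b", "c2", "d", "e"),
    parent = c(NA,   "c1", "c1", "c1", "c1", "c2"),
    x      = c(0,    0,    60,   120,  60,   120),
    y      = c(0,    60,   60,   0,    0,    0),
    stringsAsFactors = FALSE)
  edges <- data.frame(
    id = c("a--b", "b--d", "d--e"),
    source = c("a", "b", "d"),
    target = c("b", "d", "e"),
    stringsAsFactors = FALSE)
  build_graph(nodes, edges)
}

#' Parameters for the random compound-graph generator
#'
#' @param n_leaf_nodes number of plain (leaf) nodes.
#' @param n_compounds number of compound nodes.
#' @param max_depth deepest allowed inclusion level (>= 1).
#' @param edge_density expected number of adjacency edges per node.
#' @param p_intergraph probability that a sampled edge is forced to join
#'   nodes with different owners.
#' @param seed integer seed; generation is a pure function of it.
#' @return a list of class `cg_generator_params`.
#' @export
generator_params <- function(n_leaf_nodes = 20, n_compounds = 4,
                             max_depth = 3, edge_density = 1.5,
                             p_intergraph = 0.3, seed = 1L) {
  stopifnot(n_leaf_nodes >= 0, n_compounds >= 0, max_depth >= 1,
            edge_density >= 0, p_intergraph >= 0, p_intergraph <= 1)
  if (p_intergraph > 0 && n_compounds == 0)
    stop("infeasible parameters: inter-graph edges require compounds")
  structure(list(n_leaf_nodes = as.integer(n_leaf_nodes),
                 n_compounds = as.integer(n_compounds),
                 max_depth = as.integer(max_depth),
                 edge_density = edge_density,
                 p_intergraph = p_intergraph,
                 seed = as.integer(seed)),
            class = "cg_generator_params")
}

#' Generate a seeded random compound graph
#'
#' The inclusion tree is built first by random recursive attachment bounded
#' by `max_depth`, then edges are sampled between node pairs, forcing
#' different owners with probability `p_intergraph` and resampling any pair
#' that would violate the ancestor/descendant rule, so the result is valid
#' by construction. Node positions are scattered uniformly in a square that
#' scales with the node count.
#'
#' @param params a [generator_params()] list.
#' @return a valid `compound_graph`.
#' @examples
#' g <- generate_compound_graph(generator_params(n_leaf_nodes = 10, seed = 7))
#' length(validate_graph(g)) == 0
#' @export
generate_compound_graph <- function(params = generator_params()) {
  stopifnot(inherits(params, "cg_generator_params"))
  cg_with_seed(params$seed, cg_generate_impl(params))
}

cg_generate_impl <- function(params) {
  ncomp <- params$n_compounds
  nleaf <- params$n_leaf_nodes
  total <- ncomp + nleaf
  if (total == 0L)
    return(build_graph(NULL, NULL))
  comp_ids <- if (ncomp) sprintf("c%d", seq_len(ncomp)) else character()
  leaf_ids <- if (nleaf) sprintf("n%d", seq_len(nleaf)) else character()
  parent <- character(0)
  level <- integer(0)
  for (cid in comp_ids) {
    ## compounds may own nodes, so they must sit above the deepest level
    host <- names(level)[level < params$max_depth - 1L]
    pick <- sample(c(NA_character_, host), 1L)
    parent[cid] <- pick
    level[cid] <- if (is.na(pick)) 0L else level[[pick]] + 1L
  }
  for (nid in leaf_ids) {
    pick <- sample(c(NA_character_, comp_ids), 1L)
    parent[nid] <- pick
    level[nid] <- if (is.na(pick)) 0L else level[[pick]] + 1L
  }
  side <- 50 * sqrt(total)
  ids <- c(comp_ids, leaf_ids)
  nodes <- data.frame(id = ids, parent = unname(parent[ids]),
                      x = stats::runif(total, -side / 2, side / 2),
                      y = stats::runif(total, -side / 2, side / 2),
                      stringsAsFactors = FALSE)

  ## ancestor test over the parent map (graph not built yet)
  anc <- function(id) {
    out <- character()
    cur <- parent[[id]]
    while (!is.na(cur)) { out <- c(out, cur); cur <- parent[[cur]] }
    out
  }
  related <- function(a, b) a %in% anc(b) || b %in% anc(a)

  n_edges <- round(params$edge_density * total)
  pairs <- character()
  src <- tgt <- character()
  attempts_cap <- 200L
  for (k in seq_len(n_edges)) {
    want_inter <- stats::runif(1) < params$p_intergraph
    placed <- FALSE
    for (att in seq_len(attempts_cap)) {
      uv <- sample(ids, 2L)
      if (related(uv[1], uv[2])) next
      same_owner <- identical(parent[[uv[1]]], parent[[uv[2]]]) ||
        (is.na(parent[[uv[1]]]) && is.na(parent[[uv[2]]]))
      if (want_inter == same_owner) next
      key <- paste(sort(uv), collapse = "|")
      if (key %in% pairs) next
      pairs <- c(pairs, key)
      src <- c(src, uv[1]); tgt <- c(tgt, uv[2])
      placed <- TRUE
      break
    }
    if (!placed) {
      ## density beats the owner constraint when no matching pair exists
      for (att in seq_len(attempts_cap)) {
        uv <- sample(ids, 2L)
        if (related(uv[1], uv[2])) next
        key <- paste(sort(uv), collapse = "|")
        if (key %in% pairs) next
        pairs <- c(pairs, key)
        src <- c(src, uv[1]); tgt <- c(tgt, uv[2])
        break
      }
    }
  }
  edges <- if (length(src))
    data.frame(id = sprintf("e%d", seq_along(src)), source = src, target = tgt,
               stringsAsFactors = FALSE) else NULL
  build_graph(nodes, edges)
}

#' Generate a plain lattice of nodes
#'
#' `rows * cols` parentless 30x30 nodes at lattice positions with the given
#' spacing and no edges; the standard stage for fisheye adjustment tests.
#'
#' @param rows,cols positive lattice dimensions.
#' @param spacing distance between neighboring centres in drawing units.
#' @return a valid `compound_graph`.
#' @export
generate_grid_graph <- function(rows, cols, spacing = 50) {
  stopifnot(rows >= 1, cols >= 1, spacing > 0)
  ij <- expand.grid(i = seq_len(rows), j = seq_len(cols))
  nodes <- data.frame(id = sprintf("r%dc%d", ij$i, ij$j),
                      parent = NA_character_,
                      x = (ij$j - 1) * spacing,
                      y = (ij$i - 1) * spacing,
                      stringsAsFactors = FALSE)
  build_graph(nodes, NULL)
}
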