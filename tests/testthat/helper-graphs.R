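# Shared fixtures, normalisers and independent oracles for the suite.

# operations without post-op layout / fisheye: keeps structural tests fast
# and lets layout behaviour be tested in isolation
opt_fast <- function(...) {
  cg_options(layout_after_op = "none", fisheye = FALSE, ...)
}

# order-insensitive view of a graph for whole-state equality
norm_graph <- function(g) {
  g$nodes <- lapply(g$nodes[sort(names(g$nodes))], function(nd) {
    if (!is.null(nd$store)) {
      nd$store$nodes <- nd$store$nodes[sort(as.character(names(nd$store$nodes)))]
      nd$store$edges <- nd$store$edges[sort(as.character(names(nd$store$edges)))]
      if (!length(nd$store$nodes)) nd$store$nodes <- list()
      if (!length(nd$store$edges)) nd$store$edges <- list()
    }
    nd
  })
  g$edges <- g$edges[sort(as.character(names(g$edges)))]
  if (!length(g$nodes)) g$nodes <- list()
  if (!length(g$edges)) g$edges <- list()
  g$archived_originals <-
    g$archived_originals[sort(as.character(names(g$archived_originals)))]
  if (!length(g$archived_originals)) g$archived_originals <- list()
  g
}

# active topology: endpoint multisets, kinds, original pointers, ownership.
# Permutations of a collapse set must agree on this; where the archived
# originals are parked (store vs graph registry) legitimately depends on the
# order when set members are nested in each other, so the registry is only
# part of the full signature.
active_topology <- function(g) {
  ids <- sort(names(g$edges))
  list(
    nodes = sort(names(g$nodes)),
    parents = vapply(g$nodes[sort(names(g$nodes))], `[[`, "", "parent"),
    edges = lapply(g$edges[ids], function(e)
      list(ends = sort(c(e$source, e$target)), kind = e$kind,
           ref = e$original_ref)))
}

topo_signature <- function(g) {
  c(active_topology(g),
    list(archived = sort(as.character(names(g$archived_originals)))))
}

# igraph over the visible sub-network (isolated visible nodes included)
visible_igraph <- function(g) {
  vn <- sort(compoundgraph:::cg_visible_nodes(g))
  ve <- compoundgraph:::cg_visible_edges(g)
  el <- do.call(rbind, lapply(ve, function(eid) {
    e <- g$edges[[eid]]
    c(e$source, e$target)
  }))
  igraph::graph_from_data_frame(
    if (is.null(el)) data.frame(from = character(), to = character())
    else data.frame(from = el[, 1], to = el[, 2]),
    directed = FALSE, vertices = data.frame(name = vn))
}

# brute-force quadrant score table, written independently of the package path
oracle_quadrant_scores <- function(g, anchor) {
  ig <- visible_igraph(g)
  d <- igraph::distances(ig, v = anchor)[1, ]
  a <- g$nodes[[anchor]]
  sc <- c(I = 0L, II = 0L, III = 0L, IV = 0L)
  for (id in names(d)) {
    if (id == anchor || !is.finite(d[[id]]) || d[[id]] > 2) next
    b <- g$nodes[[id]]
    dx <- b$x - a$x; dy <- b$y - a$y
    q <- if (dy >= 0) (if (dx >= 0) "I" else "II")
         else (if (dx <= 0) "III" else "IV")
    sc[q] <- sc[q] + if (d[[id]] == 1) 3L else 1L
  }
  sc
}

# random valid graph of moderate size for property loops
random_graph <- function(seed, n = 20, compounds = 4, p_inter = 0.3) {
  generate_compound_graph(generator_params(
    n_leaf_nodes = n, n_compounds = compounds, max_depth = 3,
    edge_density = 1.5, p_intergraph = p_inter, seed = seed))
}

expect_valid <- function(g) {
  v <- validate_graph(g)
  expect_length(v, 0)
  invisible(g)
}
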