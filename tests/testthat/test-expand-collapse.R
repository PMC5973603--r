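# Structural behaviour of collapse/expand; layout hooks are disabled via
# opt_fast() so only the meta-edge algebra is under test here.

test_that("collapsing c2 in the worked example creates the expected meta edge", {
  g <- example_compound_graph()
  res <- collapse_node(g, "c2", opt_fast())
  gc <- expect_valid(res$graph)

  m <- gc$edges[["meta:d--e"]]
  expect_equal(m$kind, "meta")
  expect_setequal(c(m$source, m$target), c("d", "c2"))
  expect_equal(m$original_ref, "d--e")
  expect_named(gc$archived_originals, "d--e")
  expect_null(gc$nodes$e)
  expect_true(gc$nodes$c2$collapsed)
  expect_equal(gc$nodes$c2$width, 30)
  expect_equal(gc$nodes$c2$height, 30)
  expect_equal(res$report$created_meta_edges, "meta:d--e")
  expect_true(res$report$edge_touch_count >=
                length(res$report$created_meta_edges) +
                length(res$report$discarded_meta_edges) +
                length(res$report$reconnected_meta_edges))
})

test_that("collapsing the outermost compound archives everything, no meta edges", {
  g <- example_compound_graph()
  res <- collapse_node(g, "c1", opt_fast())
  gc <- expect_valid(res$graph)
  expect_equal(names(gc$nodes), "c1")
  expect_length(gc$edges, 0)
  expect_length(gc$archived_originals, 0)
  expect_setequal(names(gc$nodes$c1$store$nodes), c("a", "b", "c2", "d", "e"))
  expect_setequal(names(gc$nodes$c1$store$edges), c("a--b", "b--d", "d--e"))
})

test_that("collapse preconditions are enforced", {
  g <- example_compound_graph()
  expect_error(collapse_node(g, "zz", opt_fast()), "unknown node")
  expect_error(collapse_node(g, "a", opt_fast()), "not a collapsible compound")
  gc <- collapse_node(g, "c2", opt_fast())$graph
  expect_error(collapse_node(gc, "c2", opt_fast()), "already collapsed")
  expect_error(expand_node(g, "a", opt_fast()), "not collapsed")
})

three_level_fixture <- function() {
  build_graph(
    data.frame(id = c("c", "cs", "s", "y"), parent = c(NA, "c", "cs", NA)),
    data.frame(id = "s--y", source = "s", target = "y"))
}

test_that("nested collapse reconnects the existing meta edge instead of duplicating", {
  g <- three_level_fixture()
  g1 <- collapse_node(g, "cs", opt_fast())$graph
  expect_setequal(c(g1$edges[["meta:s--y"]]$source, g1$edges[["meta:s--y"]]$target),
                  c("cs", "y"))
  res <- collapse_node(g1, "c", opt_fast())
  g2 <- expect_valid(res$graph)
  # no new meta edge; the one meta edge moved its inner endpoint up to c
  expect_length(res$report$created_meta_edges, 0)
  expect_length(res$report$reconnected_meta_edges, 1)
  expect_setequal(c(g2$edges[["meta:s--y"]]$source, g2$edges[["meta:s--y"]]$target),
                  c("c", "y"))
  expect_named(g2$archived_originals, "s--y")
})

test_that("expanding resolves meta edges per the inner state", {
  # outer expand retargets the meta edge to the still-collapsed inner compound
  g2 <- collapse_node(collapse_node(three_level_fixture(), "cs", opt_fast())$graph,
                      "c", opt_fast())$graph
  res <- expand_node(g2, "c", opt_fast())
  g3 <- expect_valid(res$graph)
  m <- g3$edges[["meta:s--y"]]
  expect_setequal(c(m$source, m$target), c("cs", "y"))
  expect_equal(m$original_ref, "s--y")
  expect_named(g3$archived_originals, "s--y")
  # inner expand then discards the meta edge and reactivates the original
  res2 <- expand_node(g3, "cs", opt_fast())
  g4 <- expect_valid(res2$graph)
  expect_equal(res2$report$discarded_meta_edges, "meta:s--y")
  expect_named(g4$edges, "s--y")
  expect_length(g4$archived_originals, 0)
})

test_that("collapse then expand is the identity on the whole state", {
  g <- example_compound_graph()
  rt <- expand_node(collapse_node(g, "c2", opt_fast())$graph, "c2", opt_fast())$graph
  expect_equal(norm_graph(rt), norm_graph(g))
})

test_that("expand restores children around the compound's current centre", {
  g <- example_compound_graph()
  gc <- collapse_node(g, "c2", opt_fast())$graph
  rel_e <- gc$nodes$c2$store$nodes$e
  # drag the collapsed proxy
  gc$nodes$c2$x <- gc$nodes$c2$x + 100
  gc$nodes$c2$y <- gc$nodes$c2$y - 40
  ge <- expand_node(gc, "c2", opt_fast())$graph
  expect_equal(ge$nodes$e$x, gc$nodes$c2$x + rel_e$x)
  expect_equal(ge$nodes$e$y, gc$nodes$c2$y + rel_e$y)
})

test_that("collapse_set works bottom-up and skips non-compounds", {
  g <- example_compound_graph()
  res <- collapse_set(g, c("c1", "c2", "a"), recursive = TRUE, options = opt_fast())
  gc <- expect_valid(res$graph)
  expect_equal(names(gc$nodes), "c1")
  expect_length(gc$edges, 0)
  expect_true("a" %in% res$report$skipped)
  # c2 collapsed inside c1's store
  expect_true(gc$nodes$c1$store$nodes$c2$collapsed)
  expect_named(gc$nodes$c1$store$nodes$c2$store$nodes, "e")

  res0 <- collapse_set(g, character(), options = opt_fast())
  expect_equal(norm_graph(res0$graph), norm_graph(g))
  expect_length(res0$report$archived_elements, 0)
})

test_that("two sibling compounds joined by one edge yield one meta edge, either order", {
  g <- build_graph(
    data.frame(id = c("A", "B", "u", "v"), parent = c(NA, NA, "A", "B")),
    data.frame(id = "u--v", source = "u", target = "v"))
  for (ord in list(c("A", "B"), c("B", "A"))) {
    gg <- g
    for (n in ord) gg <- collapse_node(gg, n, opt_fast())$graph
    expect_valid(gg)
    metas <- Filter(function(e) e$kind == "meta", gg$edges)
    expect_length(metas, 1)
    expect_setequal(c(metas[[1]]$source, metas[[1]]$target), c("A", "B"))
    expect_equal(metas[[1]]$original_ref, "u--v")
  }
})

test_that("collapsing a node set is permutation invariant", {
  for (seed in 1:8) {
    g <- random_graph(seed, n = 15, compounds = 5)
    comps <- collapsible_nodes(g)
    if (length(comps) < 2) next
    set.seed(seed)
    pick <- sample(comps, min(3, length(comps)))
    perms <- list(pick, rev(pick))
    if (length(pick) == 3) perms <- c(perms, list(pick[c(2, 3, 1)]))
    sigs <- lapply(perms, function(p) {
      gg <- g
      for (n in p) {
        if (!is.null(gg$nodes[[n]]) && node_op_state(gg, n)$collapsible)
          gg <- collapse_node(gg, n, opt_fast())$graph
      }
      expect_valid(gg)
      active_topology(gg)
    })
    for (s in sigs[-1]) expect_equal(s, sigs[[1]])
  }
})

test_that("expand_all after arbitrary collapse sequences restores the pristine graph", {
  for (seed in 1:10) {
    g <- random_graph(seed)
    sig0 <- topo_signature(g)
    gg <- g
    set.seed(100 + seed)
    for (step in 1:6) {
      doable <- collapsible_nodes(gg)
      if (!length(doable)) break
      gg <- collapse_node(gg, sample(doable, 1), opt_fast())$graph
      expect_valid(gg)
    }
    ge <- expand_all(gg, opt_fast())$graph
    expect_valid(ge)
    expect_length(ge$archived_originals, 0)
    expect_length(Filter(function(e) e$kind == "meta", ge$edges), 0)
    expect_equal(topo_signature(ge), sig0)
  }
})

test_that("original edges are never lost across operations", {
  all_original_ids <- function(g) {
    ids <- names(Filter(function(e) e$kind == "original", g$edges))
    ids <- c(ids, names(g$archived_originals))
    walk <- function(nodes) {
      for (nd in nodes) {
        if (!is.null(nd$store)) {
          ids <<- c(ids, names(Filter(function(e) e$kind == "original",
                                      nd$store$edges)))
          walk(nd$store$nodes)
        }
      }
    }
    walk(g$nodes)
    sort(ids)
  }
  g <- random_graph(3)
  want <- all_original_ids(g)
  gg <- g
  set.seed(99)
  for (step in 1:8) {
    cs <- collapsible_nodes(gg); es <- expandable_nodes(gg)
    if (length(cs) && (step %% 2 == 1 || !length(es))) {
      gg <- collapse_node(gg, sample(cs, 1), opt_fast())$graph
    } else if (length(es)) {
      gg <- expand_node(gg, sample(es, 1), opt_fast())$graph
    }
    expect_equal(all_original_ids(gg), want)
  }
})

test_that("edge touches stay linear in collapsed content plus incident edges", {
  for (seed in 1:6) {
    g <- random_graph(seed, n = 30, compounds = 5)
    for (cid in collapsible_nodes(g)) {
      desc <- compoundgraph:::cg_descendants(g, cid)
      incident <- sum(vapply(g$edges, function(e)
        e$source %in% desc || e$target %in% desc, logical(1)))
      res <- collapse_node(g, cid, opt_fast())
      expect_lte(res$report$edge_touch_count, 2 * (length(desc) + incident))
    }
  }
})

test_that("node_op_state and the set filters reflect collapse state", {
  g <- example_compound_graph()
  expect_equal(node_op_state(g, "c2"), list(collapsible = TRUE, expandable = FALSE))
  expect_equal(node_op_state(g, "a"), list(collapsible = FALSE, expandable = FALSE))
  gc <- collapse_node(g, "c2", opt_fast())$graph
  expect_equal(node_op_state(gc, "c2"), list(collapsible = FALSE, expandable = TRUE))
  expect_setequal(collapsible_nodes(g), c("c1", "c2"))
  expect_equal(expandable_nodes(gc), "c2")
})

test_that("collapsed_children exposes stored content at the requested depth", {
  g <- example_compound_graph()
  gc <- collapse_node(g, "c2", opt_fast())$graph
  expect_equal(collapsed_children(gc, "c2", "direct"),
               list(nodes = "e", edges = character()))
  ga <- collapse_all(g, opt_fast())$graph
  expect_equal(collapsed_children(ga, "c1", "recursive"),
               list(nodes = c("a", "b", "c2", "d", "e"),
                    edges = c("a--b", "b--d")))
  expect_equal(collapsed_children(g, mode = "all_graph"),
               list(nodes = character(), edges = character()))
  expect_error(collapsed_children(g, "c2", "direct"), "not collapsed")
})

test_that("event callbacks fire around each node operation in bulk variants", {
  log <- character()
  opts <- opt_fast(
    before_collapse = function(g, id) log <<- c(log, paste0("pre:", id)),
    after_collapse = function(g, id) log <<- c(log, paste0("post:", id)))
  collapse_set(example_compound_graph(), c("c1", "c2"), recursive = TRUE,
               options = opts)
  expect_equal(log, c("pre:c2", "post:c2", "pre:c1", "post:c1"))
})
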