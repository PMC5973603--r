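test_that("hiding a node hides its incident edges implicitly", {
  g <- example_compound_graph()
  res <- hide_elements(g, "d", opt_fast())
  expect_valid(res$graph)
  expect_equal(res$report$hidden_elements, c("b--d", "d", "d--e"))
  expect_length(compoundgraph:::cg_visible_nodes(res$graph), 5)
  expect_setequal(compoundgraph:::cg_visible_edges(res$graph), "a--b")
  # hidden elements keep coordinates
  expect_equal(res$graph$nodes$d$x, g$nodes$d$x)
})

test_that("hide of nothing / of everything behaves", {
  g <- example_compound_graph()
  res0 <- hide_elements(g, character(), opt_fast())
  expect_equal(norm_graph(res0$graph), norm_graph(g))
  resA <- hide_elements(g, names(g$nodes), opt_fast())
  expect_length(compoundgraph:::cg_visible_nodes(resA$graph), 0)
  expect_valid(resA$graph)
  expect_error(hide_elements(g, "ghost", opt_fast()), "unknown element")
})

test_that("quadrant scores follow the +3 / +1 rule with I<II<III<IV ties", {
  # one first-degree neighbor in quadrant I
  q <- build_graph(data.frame(id = c("A", "B"), x = c(0, 10), y = c(0, 10)),
                   data.frame(source = "A", target = "B"))
  t1 <- quadrant_scores(q, "A")
  expect_equal(t1$scores, c(I = 3L, II = 0L, III = 0L, IV = 0L))
  expect_equal(t1$chosen, "II")

  # second-degree neighbor adds 1 to its own quadrant
  q2 <- build_graph(
    data.frame(id = c("A", "B", "C"), x = c(0, 10, -10), y = c(0, 10, -10)),
    data.frame(source = c("A", "B"), target = c("B", "C")))
  t2 <- quadrant_scores(q2, "A")
  expect_equal(t2$scores, c(I = 3L, II = 0L, III = 1L, IV = 0L))
  expect_equal(t2$chosen, "II")

  # no neighbors: all zeros, first quadrant wins the tie
  iso <- build_graph(data.frame(id = "A"))
  t3 <- quadrant_scores(iso, "A")
  expect_equal(unname(t3$scores), rep(0L, 4))
  expect_equal(t3$chosen, "I")

  expect_error(quadrant_scores(q, "nope"), "unknown node")
  qh <- hide_elements(q, "A", opt_fast())$graph
  expect_error(quadrant_scores(qh, "A"), "hidden")
})

test_that("boundary points count toward the lower-numbered quadrant", {
  mk <- function(x, y) {
    g <- build_graph(data.frame(id = c("A", "B"), x = c(0, x), y = c(0, y)),
                     data.frame(source = "A", target = "B"))
    names(which(quadrant_scores(g, "A")$scores > 0))
  }
  expect_equal(mk(0, 10), "I")
  expect_equal(mk(-10, 0), "II")
  expect_equal(mk(0, -10), "III")
  expect_equal(mk(10, 0), "I")
})

test_that("quadrant scores equal the brute-force oracle on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:20) {
    g <- random_graph(seed, n = 25)
    vis <- compoundgraph:::cg_visible_nodes(g)
    set.seed(seed)
    for (anchor in sample(vis, 3)) {
      expect_equal(quadrant_scores(g, anchor)$scores,
                   oracle_quadrant_scores(g, anchor),
                   info = paste("seed", seed, "anchor", anchor))
    }
  }
})

test_that("hidden nodes never contribute to quadrant scores", {
  g <- build_graph(
    data.frame(id = c("A", "B", "C"), x = c(0, 10, -10), y = c(0, 10, -10)),
    data.frame(source = c("A", "B"), target = c("B", "C")))
  gh <- hide_elements(g, "B", opt_fast())$graph
  expect_equal(unname(quadrant_scores(gh, "A")$scores), rep(0L, 4))
})

test_that("placement draws land in the chosen quadrant at ~ideal edge length", {
  g <- build_graph(
    data.frame(id = c("A", "B", "N", "Z"), x = c(0, -10, 0, 500), y = c(0, 10, 0, 500)),
    data.frame(source = c("A", "A"), target = c("B", "N")))
  gh <- hide_elements(g, c("N", "Z"), opt_fast())$graph
  # visible neighbor B sits in II; ties put the chosen quadrant at I
  p <- placement_params(seed = 11)
  pos <- place_unhidden_level(gh, "A", "N", p)
  r <- sqrt(sum(pos["N", ]^2))
  expect_gte(r, 0.9 * p$ideal_edge_length)
  expect_lte(r, 1.1 * p$ideal_edge_length)
  ang <- atan2(pos["N", "y"], pos["N", "x"]) * 180 / pi
  expect_gte(ang, 15); expect_lte(ang, 75)

  expect_identical(place_unhidden_level(gh, "A", "N", p), pos)
  expect_equal(nrow(place_unhidden_level(gh, "A", character(), p)), 0)
  expect_error(place_unhidden_level(gh, "A", "Z", p), "not adjacent")
})

test_that("show reveals level by level with interleaved layout", {
  ch <- build_graph(data.frame(id = c("p", "q", "r"), x = c(0, 50, 100)),
                    data.frame(source = c("p", "q"), target = c("q", "r")))
  h <- hide_elements(ch, c("q", "r"), opt_fast())$graph
  pp <- placement_params(seed = 3)
  res <- show_elements(h, c("q", "r"), opt_fast(), pp)
  expect_valid(res$graph)
  expect_equal(res$report$levels, list(`1` = "q", `2` = "r"))
  # one layout burst per level
  expect_gte(res$report$layout_iterations, 2 * pp$iterations_per_level)
  # placements happened at ~ideal edge length from the recorded anchor
  for (pl in res$report$placements) {
    d <- sqrt((pl$x - pl$anchor_x)^2 + (pl$y - pl$anchor_y)^2)
    expect_gte(d, 0.9 * pp$ideal_edge_length)
    expect_lte(d, 1.1 * pp$ideal_edge_length)
  }
})

test_that("show places a revealed neighbor near its visible anchor", {
  g <- example_compound_graph()
  h <- hide_elements(g, "e", opt_fast())$graph
  pp <- placement_params(seed = 7)
  res <- show_elements(h, "e", opt_fast(), pp)
  pl <- res$report$placements$e
  expect_equal(pl$anchor, "d")
  d <- sqrt((pl$x - pl$anchor_x)^2 + (pl$y - pl$anchor_y)^2)
  expect_gte(d, 0.9 * pp$ideal_edge_length)
  expect_lte(d, 1.1 * pp$ideal_edge_length)
})

test_that("hide then show is the identity on visible topology", {
  vis_topo <- function(g) {
    ve <- compoundgraph:::cg_visible_edges(g)
    list(nodes = sort(compoundgraph:::cg_visible_nodes(g)),
         edges = lapply(g$edges[sort(ve)], function(e)
           sort(c(e$source, e$target))))
  }
  for (seed in 1:6) {
    g <- random_graph(seed, n = 15, compounds = 2)
    want <- vis_topo(g)
    set.seed(seed)
    pick <- sample(grep("^n", names(g$nodes), value = TRUE), 4)
    h <- hide_elements(g, pick, opt_fast())$graph
    s <- show_elements(h, pick, opt_fast(), placement_params(seed = seed))$graph
    expect_valid(s)
    expect_equal(vis_topo(s), want)
  }
  # whole-graph round trip: detached nodes return at stored coordinates
  g <- example_compound_graph()
  h <- hide_elements(g, names(g$nodes), opt_fast())$graph
  s <- show_elements(h, names(g$nodes), opt_fast())$graph
  expect_equal(vis_topo(s), vis_topo(g))
})

test_that("show levels match an independent BFS from the visible frontier", {
  skip_if_not_installed("igraph")
  for (seed in 1:6) {
    g <- random_graph(seed, n = 15, compounds = 2)
    set.seed(seed * 7)
    pick <- sample(grep("^n", names(g$nodes), value = TRUE), 5)
    h <- hide_elements(g, pick, opt_fast())$graph
    res <- show_elements(h, pick, opt_fast(), placement_params(seed = seed))

    # oracle: BFS over the post-show visible network from the pre-show
    # visible frontier
    ig <- visible_igraph(res$graph)
    frontier <- compoundgraph:::cg_visible_nodes(h)
    frontier <- intersect(frontier, igraph::V(ig)$name)
    d <- suppressWarnings(igraph::distances(ig, v = frontier))
    dmin <- apply(d, 2, min)
    for (lv in setdiff(names(res$report$levels), "detached")) {
      for (id in res$report$levels[[lv]])
        expect_equal(unname(dmin[id]), as.numeric(lv))
    }
    for (id in res$report$levels[["detached"]])
      expect_false(is.finite(dmin[id]))
  }
})

test_that("after show no two visible leaves overlap by more than half the smaller box", {
  overlap_frac <- function(a, b) {
    ox <- max(0, min(a$x + a$width / 2, b$x + b$width / 2) -
                 max(a$x - a$width / 2, b$x - b$width / 2))
    oy <- max(0, min(a$y + a$height / 2, b$y + b$height / 2) -
                 max(a$y - a$height / 2, b$y - b$height / 2))
    ox * oy / min(a$width * a$height, b$width * b$height)
  }
  for (seed in 1:4) {
    g <- random_graph(seed, n = 12, compounds = 2)
    set.seed(seed)
    pick <- sample(grep("^n", names(g$nodes), value = TRUE), 5)
    h <- hide_elements(g, pick, opt_fast())$graph
    s <- show_elements(h, pick, opt_fast(), placement_params(seed = seed))$graph
    leaves <- compoundgraph:::cg_particles(s)
    for (i in seq_along(leaves)) {
      for (j in seq_len(i - 1)) {
        expect_lte(overlap_frac(s$nodes[[leaves[i]]], s$nodes[[leaves[j]]]), 0.5)
      }
    }
  }
})

test_that("highlight state management follows first-use semantics", {
  g <- example_compound_graph()
  r <- set_highlight(g, "b", "highlight")
  expect_true(r$graph$highlight_active)
  expect_true(r$graph$nodes$b$highlighted)
  expect_false(any(vapply(r$graph$nodes[setdiff(names(r$graph$nodes), "b")],
                          `[[`, logical(1), "highlighted")))

  rn <- set_highlight(g, "b", "highlight_neighbors")
  hn <- Filter(function(i) rn$graph$nodes[[i]]$highlighted, names(rn$graph$nodes))
  he <- Filter(function(i) rn$graph$edges[[i]]$highlighted, names(rn$graph$edges))
  expect_setequal(hn, c("a", "b", "d"))
  expect_setequal(he, c("a--b", "b--d"))

  rc <- set_highlight(rn$graph, mode = "remove_all")
  expect_false(rc$graph$highlight_active)
  expect_false(any(vapply(rc$graph$nodes, `[[`, logical(1), "highlighted")))
  expect_false(any(vapply(rc$graph$edges, `[[`, logical(1), "highlighted")))

  expect_error(set_highlight(g, "ghost", "highlight"), "unknown element")
})

test_that("an injectable neighbor provider drives the neighbor modes", {
  g <- example_compound_graph()
  r <- set_highlight(g, "b", "highlight_neighbors",
                     neighbor_provider = function(graph, id) "e")
  hn <- Filter(function(i) r$graph$nodes[[i]]$highlighted, names(r$graph$nodes))
  expect_setequal(hn, c("b", "e"))
})
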