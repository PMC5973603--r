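# compoundgraph

Complexity management for nested (compound) networks in R.

Large relational maps — biological pathway maps in particular, where SBGN-style
diagrams nest molecules inside complexes, compartments and sub-maps — quickly
become unreadable. The standard remedies are *collapsing* compound nodes,
*hiding* currently irrelevant sub-networks, and revealing them again on demand.
Done naively, each of these operations scrambles the drawing and destroys the
user's **mental map** (their memory of where things were). `compoundgraph` is a
headless library + CLI that performs these operations with careful structural
bookkeeping and layout adjustment, for anyone building network analysis or
visualization pipelines over hierarchical graphs.

## The model

A compound graph is C = (V, E, F): nodes V, undirected adjacency edges E, and
inclusion edges F that must form a rooted tree; no adjacency edge may connect a
node to one of its ancestors or descendants. An edge whose endpoints have
different owners is an *inter-graph edge*.

Four mechanisms cooperate:

- **Collapse / expand with meta edges.** Collapsing a compound `c` archives its
  (recursive) content into a store and replaces every edge crossing `c`'s
  boundary by a *meta edge* `{c, outside-end}` carrying a single pointer to the
  archived original; an edge that is already a meta edge is merely reconnected.
  Expanding resolves each incident meta edge back: discard-and-reactivate when
  both original endpoints are active again, otherwise reconnect to the
  outermost still-collapsed compound containing the endpoint. The invariants —
  exactly one meta edge per archived original, order-independent results,
  touches linear in the collapsed content — hold at all times.
- **Incremental force layout.** A spring embedder (springs `k_s (d − l_e)`,
  inverse-square repulsion over box-boundary distance, weak gravity toward the
  owning compound) whose per-iteration displacement is capped by a
  simulated-annealing temperature `T_i = T_0 · cooling^i`. Incremental runs
  start from the current coordinates with a *low* `T_0 = 0.3 l`, so the drawing
  tightens without drastic moves; static runs start hot (`3 l`).
- **Fisheye space adjustment.** Before an expand, surrounding nodes are pushed
  away from the anchor by the change in its required space
  `(T_x, T_y) = (Δwidth/2, Δheight/2)`, component-wise away from the anchor's
  axes — signs of relative coordinates are preserved and shrinking back is the
  exact inverse.
- **Quadrant heuristic for unhiding.** A node's neighborhood is split into the
  four axis-aligned quadrants; each visible first-degree neighbor adds +3 and
  each second-degree neighbor +1 to its quadrant. Newly revealed neighbors are
  placed roughly one ideal edge length into the least crowded quadrant, level
  by level, with incremental layout interleaved between levels.

## Worked example

The package ships a six-node example: compound `c1` contains `a`, `b`, `d` and
compound `c2`, which contains `e`; edges `{a,b}`, `{b,d}` and the single
inter-graph edge `{d,e}`.

```r
library(compoundgraph)
g <- example_compound_graph()
g
#> <compound_graph> 6 nodes (2 compound), 3 active edges (0 meta), 0 archived originals

res <- collapse_node(g, "c2", cg_options(layout_after_op = "none"))
res$report
#> <op report> collapse_node(c2): +1 meta, -0 meta, 0 reconnected, 2 archived,
#>   0 restored, 0 layout iter, 2 edge touches
```

Collapsing `c2` archived node `e` and the original edge `d--e` (the two
archived elements) and created one meta edge standing in for it:

```r
m <- res$graph$edges[["meta:d--e"]]
c(m$source, m$target, m$original_ref)
#> "c2" "d" "d--e"

quadrant_scores(res$graph, "d")
#> <quadrant scores> I=6 II=1 III=0 IV=0 chosen: III
```

Around `d` the first-degree neighbors `b` and `c2` (3 each) crowd quadrant I
and the second-degree neighbor `a` adds 1 to quadrant II, so newly revealed
neighbors of `d` would be placed in quadrant III. Expanding restores the
original topology exactly (here with the default incremental polishing layout):

```r
back <- expand_node(res$graph, "c2", cg_options())
back$graph
#> <compound_graph> 6 nodes (2 compound), 3 active edges (0 meta), 0 archived originals
```

The same pipeline is available from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/compoundgraph.R", package="compoundgraph"))')
Rscript "$CLI" generate --leaf-nodes 30 --compounds 6 --seed 7 --out net.graphml
Rscript "$CLI" collapse --nodes c1,c2 --in net.graphml --out collapsed.graphml
Rscript "$CLI" render   --in collapsed.graphml --out map.svg
```

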