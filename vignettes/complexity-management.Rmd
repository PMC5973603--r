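---
title: "Complexity management for compound graphs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Complexity management for compound graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(compoundgraph)
```

## The problem

Hierarchically organised networks — molecular complexes inside compartments
inside sub-maps, modules inside systems — are modelled here as *compound
graphs* C = (V, E, F): the inclusion edges F form a rooted tree over the
nodes, and adjacency edges never connect a node to an ancestor or descendant.
Interactive analysis of such networks needs two complexity-management
families: collapse/expand of compound nodes, and hide/show of arbitrary
sub-networks. Both change topology *and* geometry, and both can destroy the
user's mental map — the remembered relative positions of nodes — unless the
structural bookkeeping is exact and the layout is adjusted conservatively.
`compoundgraph` implements both families headlessly, with the layout machinery
they need.

## Meta-edge bookkeeping

When a compound `c` collapses, its recursive content moves into `c`'s
*subgraph store* with positions recorded relative to `c`'s centre. Edges lying
wholly inside move into the store. For each edge with exactly one endpoint
inside:

* an **original** edge is archived in a graph-level registry and replaced by a
  **meta edge** `{c, outside-end}` whose only extra state is a pointer to the
  original;
* an existing **meta** edge is reconnected to `{c, outside-end}`, keeping its
  pointer.

Expanding restores the stored content around the compound's *current* centre
(it may have been dragged meanwhile) and resolves every incident meta edge
against its original: if both original endpoints are active again, the meta
edge is discarded and the original reactivated; otherwise it reconnects to the
*representative* of each endpoint — the outermost still-collapsed compound
containing it. Using the representative (rather than literally the immediate
child of `c` on the inclusion path) matters in one corner: a meta edge can
point at content nested two levels down behind an expanded intermediate
compound, and reconnecting to the intermediate would put a meta edge between
two visible nodes. The representative rule coincides with the immediate-child
rule in every ordinary case and keeps the invariants below in the deep case.

Three invariants hold after every operation and are asserted continuously by
the test suite:

1. exactly one meta edge (active or parked in a store) per archived original;
2. the **active topology** produced by collapsing a set of compounds is
   independent of the order of collapsing. Where the archived originals are
   *parked* — graph registry versus an enclosing store — can legitimately
   differ when one set member is nested inside another (collapsing the outer
   first swallows the inner edge into the store; collapsing the inner first
   routes it through the registry), which is why the order-independence
   contract is stated over active topology;
3. a full `expand_all()` after any collapse sequence restores the pristine
   topology, with an empty registry.

The work done by a collapse is linear in the collapsed content: each incident
edge is touched a bounded number of times (archive, create or reconnect), and
the `edge_touch_count` in every operation report lets callers verify this.

## The layout model

The spring embedder treats visible leaf nodes (including collapsed compounds)
as particles; expanded compound bounds are *derived* — the bounding box of
visible children plus a 10-unit margin per side — and recomputed after every
mutation and every iteration.

| parameter | default | role |
|---|---|---|
| `ideal_edge_length` (l) | 50 units | spring rest length; placement radius for reveals |
| `spring_constant` | 0.45 | force per unit extension along each edge |
| `repulsion_constant` | 4500 | inverse-square repulsion over box-boundary distance |
| `gravity_constant` | 0.25 | constant pull toward the owning compound's centre |
| `nesting_length_factor` | 0.2 | rest-length growth per nesting-level difference |
| `initial_temperature_static` | 3 l | displacement cap, hot start |
| `initial_temperature_incremental` | 0.3 l | displacement cap, cool start |
| `cooling_factor` | 0.95 | geometric cooling per iteration |
| `convergence_threshold` | 0.01 l | stop when mean displacement falls below |

The published method prescribes only the *architecture* — springs, repulsion,
temperature, and "a low initial temperature" for incremental runs — so the
constants are this package's own calibration, chosen once so that the two-node
equilibrium (spring against repulsion) lands within 25% of l; with the
defaults it sits near 1.2 l. "Low" is fixed at 0.3 l against 3 l for static
runs. Every constant is a `layout_params()` field.

Numerical choices worth knowing:

* repulsion acts over the **box-boundary distance** between node rectangles
  (compounds are large; centre distance would over-repel), clamped below at 1
  unit to avoid the singularity; coincident centres get a deterministic
  pseudo-random push direction derived from the pair index, so runs are
  reproducible;
* an edge incident to an expanded compound distributes its spring force evenly
  over the compound's visible leaf descendants;
* gravity is a constant-magnitude force; root-level particles gravitate toward
  the centroid of the visible root level. It is deliberately weak — it does
  not appear in `drawing_energy()`, and at 0.25 it cannot overpower the
  gradient terms, which is why incremental runs do not increase the energy in
  practice (the suite asserts this on the worked example and ten seeded random
  graphs, not as a theorem);
* the temperature cap yields a hard mental-map guarantee: an incremental run
  of n iterations moves no node farther than
  `0.3 l (1 − 0.95^n) / 0.05` from its start.

## Fisheye space adjustment

Expanding a node into a larger box must first open room. With growth
`(T_x, T_y) = (Δwidth/2, Δheight/2)`, every visible node outside the anchor's
own ancestor/descendant line translates **component-wise away from the
anchor's axes**: `x` by `±T_x` according to the sign of `x_b − x_a` (no move
when on the axis), `y` likewise by `±T_y`. Purely horizontal neighbors
therefore move by exactly `T_x`, purely vertical ones by exactly `T_y`, the
sign of every relative coordinate is preserved (the drawing stays a
homeomorphism of itself), gaps to the anchor never shrink, and shrinking back
is the exact inverse.

A smoother-looking alternative — translating by `(T_x cos θ, T_y sin θ)`
along the anchor-to-node direction — was considered and rejected: for
anisotropic growth (`T_x ≠ T_y`) the node's direction changes as it moves, so
the shrink-back translation no longer mirrors the expansion and round trips
drift by whole units; it can also open less room than the anchor's corner
growth requires. The component-wise rule degenerates to the same answer on the
axes and is exactly invertible everywhere. On shrinks the translation is
clamped so a node never crosses an anchor axis.

Nodes are translated individually (not as rigid top-level blocks) and all
compound bounds are re-derived afterwards; with per-component sign
preservation the two views coincide for well-separated content.

## Hide, show and the quadrant heuristic

Hiding sets a flag and nothing else: hidden elements keep coordinates, stores
and their archived state, and are excluded from *every* computation — layout
forces, distances, quadrant scores. Edge visibility is derived (an edge shows
iff it is not itself flagged and both endpoints show), so hiding a node
implicitly hides its incident edges and revealing the node brings exactly the
surviving edges back.

Showing is interleaved with layout, level by level: nodes being revealed are
partitioned by shortest-path distance (over the edges that will become
visible) to the nearest currently visible node. Per level, each node picks an
anchor — its smallest-id visible neighbor, chosen over alternatives such as an
anchor-centroid for the sake of reproducibility of the per-anchor heuristic —
and the anchor's neighborhood is scored: each visible distance-1 neighbor
adds +3 and each distance-2 neighbor +1 to the axis-aligned quadrant holding
its centre (quadrants numbered counter-clockwise in y-up model space; a node
exactly on a boundary counts toward the lower-numbered adjacent quadrant; a
distance-1 node is never also counted at distance 2, since classification is
by shortest-path distance). New nodes land in the least crowded quadrant —
ties broken I < II < III < IV — at radius `l (1 ± 0.1)` and within ±30° of the
quadrant bisector, drawn from a seeded generator in sorted-id order. After
each level, `iterations_per_level` (default 30 — "several", made concrete and
configurable) incremental iterations run before the next level is introduced.
Nodes with no path to any visible anchor reappear at their stored
coordinates.

## The synthetic generator

`generate_compound_graph()` emulates mid-size nested biological networks at
desk scale: the inclusion tree is built first (random recursive attachment
bounded by `max_depth`), then edges are sampled with a coin of probability
`p_intergraph` deciding whether a pair must straddle owners, resampling any
ancestor/descendant pair — so every output is valid by construction. Defaults
(20 leaves, 4 compounds, depth 3, 1.5 edges per node, `p_intergraph` 0.3)
give the density and nesting typical of a pathway-map neighborhood; they are
stated once and not tuned against any test. What a green property run
establishes is therefore: correctness of the bookkeeping on *random sparse
nested* topologies. What it does not establish: behaviour on scale-free hubs,
very deep nesting (depth ≫ 4), dense cliques, or real curated map geometry —
no deposited real network ships with the package.

## Degenerate inputs and small print

* Empty graphs, childless "compounds" (plain nodes), isolated nodes and empty
  element sets are all legal no-ops for the respective operations.
* Collapse requires an expanded compound with at least one child; expand
  requires a collapsed one; everything else errors early with the offending
  id. Bulk variants skip instead of erroring and report what they skipped.
* A collapsed compound takes fixed 30×30 extents at its pre-collapse centre;
  default leaf geometry is 30×30 at the origin. Both are constants, not
  options, to keep fixtures deterministic.
* Hiding a compound hides that node's flag only; it does not cascade to
  descendants (callers wanting a cascade pass the descendant set explicitly).
* `graph_stats()$max_depth` is the maximum inclusion level (root level = 0).
* Serialisation is deterministic (sorted ids, fixed numeric format), so
  writing a freshly read file is byte-identical; the JSON dialect preserves
  unknown `data` fields opaquely.

## Known limitations

Rendering is a single static SVG (no animation frames, cue hit-testing or
undo/redo); the force model is a compact spring embedder, not a faithful
multi-level CoSE reimplementation, and makes no edge-crossing guarantees;
orthogonality-preserving scaling variants of the space-adjustment family are
out of scope (only the proximity-preserving rule above is implemented).
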