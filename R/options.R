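#' Operation options
#'
#' Options shared by the expand/collapse and hide/show operations, mirroring
#' the customisation surface of interactive complexity-management tools:
#' whether an incremental layout runs after each operation, whether a
#' fisheye space adjustment precedes an expand, cue geometry for rendering,
#' and the opacity used for unhighlighted elements.
#'
#' @param layout_after_op `"incremental"` (default) to run a low-temperature
#'   incremental layout after each mutating operation, or `"none"`.
#' @param fisheye push surrounding nodes outward before an expand to make
#'   room for the restored content (default `TRUE`).
#' @param cue_size side length, in drawing units, of the plus/minus cue
#'   glyph drawn on compound nodes (default 12).
#' @param cue_line_size stroke width of the cue glyph lines (default 8).
#' @param cue_position cue placement; only `"top-left"` is supported.
#' @param unhighlighted_opacity opacity applied to elements outside the
#'   highlighted set while a highlight is active (default 0.3).
#' @param set_visibility_on_hide,set_display_on_hide which attribute hidden
#'   elements receive when serialised to the JSON dialect (defaults `FALSE`
#'   and `TRUE`).
#' @param layout layout parameters used for post-operation layouts, see
#'   [layout_params()].
#' @param before_collapse,after_collapse,before_expand,after_expand optional
#'   callbacks `function(graph, node_id)` fired around each individual node
#'   operation (also from the bulk variants).
#' @return a list of class `cg_options`.
#' @export
cg_options <- function(layout_after_op = c("incremental", "none"),
                       fisheye = TRUE,
                       cue_size = 12,
                       cue_line_size = 8,
                       cue_position = "top-left",
                       unhighlighted_opacity = 0.3,
                       set_visibility_on_hide = FALSE,
                       set_display_on_hide = TRUE,
                       layout = layout_params(),
                       before_collapse = NULL, after_collapse = NULL,
                       before_expand = NULL, after_expand = NULL) {
  layout_after_op <- match.arg(layout_after_op)
  stopifnot(cue_size > 0, cue_line_size > 0,
            unhighlighted_opacity >= 0, unhighlighted_opacity <= 1,
            identical(cue_position, "top-left"))
  structure(list(layout_after_op = layout_after_op, fisheye = isTRUE(fisheye),
                 cue_size = cue_size, cue_line_size = cue_line_size,
                 cue_position = cue_position,
                 unhighlighted_opacity = unhighlighted_opacity,
                 set_visibility_on_hide = isTRUE(set_visibility_on_hide),
                 set_display_on_hide = isTRUE(set_display_on_hide),
                 layout = layout,
                 before_collapse = before_collapse, after_collapse = after_collapse,
                 before_expand = before_expand, after_expand = after_expand),
            class = "cg_options")
}

#' Force-directed layout parameters
#'
#' The force model targets an ideal edge length `l`; springs pull edge
#' endpoints with force `spring_constant * (d - l_e)` where the per-edge rest
#' length `l_e = l * (1 + nesting_length_factor * |level difference|)`
#' lengthens inter-graph and meta edges crossing nesting levels; node pairs
#' repel with `repulsion_constant / d^2` over the clamped box-boundary
#' distance `d`; a constant gravity pulls nodes toward the centre of their
#' owning compound. Per-iteration displacement is capped by a temperature
#' `T_i = T_0 * cooling_factor^i`; incremental runs start cool (`0.3 l`) so
#' nodes cannot move drastically, static runs start hot (`3 l`).
#'
#' @param ideal_edge_length target edge length `l` in drawing units.
#' @param spring_constant spring stiffness (force per unit extension).
#' @param repulsion_constant repulsion scale (force times squared units).
#' @param gravity_constant magnitude of the constant pull toward the owning
#'   compound's centre.
#' @param nesting_length_factor fractional lengthening of the rest length per
#'   inclusion-level difference between edge endpoints.
#' @param initial_temperature_static,initial_temperature_incremental starting
#'   displacement caps for static and incremental runs.
#' @param cooling_factor geometric cooling rate in (0, 1).
#' @param max_iterations iteration cap.
#' @param convergence_threshold stop when the mean displacement of an
#'   iteration falls below this many units.
#' @param incremental start from current coordinates (`TRUE`) or from a
#'   seeded random placement (`FALSE`).
#' @param seed integer seed for the random initial placement.
#' @return a list of class `cg_layout_params`.
#' @export
layout_params <- function(ideal_edge_length = 50,
                          spring_constant = 0.45,
                          repulsion_constant = 4500,
                          gravity_constant = 0.25,
                          nesting_length_factor = 0.2,
                          initial_temperature_static = 3 * ideal_edge_length,
                          initial_temperature_incremental = 0.3 * ideal_edge_length,
                          cooling_factor = 0.95,
                          max_iterations = 500,
                          convergence_threshold = 0.01 * ideal_edge_length,
                          incremental = TRUE,
                          seed = 1L) {
  stopifnot(ideal_edge_length > 0, spring_constant > 0, repulsion_constant >= 0,
            gravity_constant >= 0, nesting_length_factor >= 0,
            initial_temperature_static > 0, initial_temperature_incremental > 0,
            cooling_factor > 0, cooling_factor < 1,
            max_iterations >= 1, convergence_threshold > 0)
  structure(list(ideal_edge_length = ideal_edge_length,
                 spring_constant = spring_constant,
                 repulsion_constant = repulsion_constant,
                 gravity_constant = gravity_constant,
                 nesting_length_factor = nesting_length_factor,
                 initial_temperature_static = initial_temperature_static,
                 initial_temperature_incremental = initial_temperature_incremental,
                 cooling_factor = cooling_factor,
                 max_iterations = as.integer(max_iterations),
                 convergence_threshold = convergence_threshold,
                 incremental = isTRUE(incremental),
                 seed = as.integer(seed)),
            class = "cg_layout_params")
}

#' Placement parameters for revealing hidden neighbors
#'
#' Newly shown neighbors are placed roughly one ideal edge length away from
#' their visible anchor, inside the least crowded quadrant, with small
#' seeded radial and angular jitter; a fixed number of incremental layout
#' iterations then runs before the next level of neighbors is introduced.
#'
#' @param ideal_edge_length placement radius `l` in drawing units.
#' @param radial_jitter radius jitter as a fraction of `l` (default 0.1).
#' @param angular_jitter degrees of jitter around the chosen quadrant's
#'   bisector (default 30, i.e. +/- 30 degrees).
#' @param iterations_per_level incremental layout iterations between levels.
#' @param seed integer seed for the placement draws.
#' @return a list of class `cg_placement_params`.
#' @export
placement_params <- function(ideal_edge_length = 50,
                             radial_jitter = 0.1,
                             angular_jitter = 30,
                             iterations_per_level = 30,
                             seed = 1L) {
  stopifnot(ideal_edge_length > 0, radial_jitter >= 0, angular_jitter >= 0,
            iterations_per_level >= 1)
  structure(list(ideal_edge_length = ideal_edge_length,
                 radial_jitter = radial_jitter,
                 angular_jitter = angular_jitter,
                 iterations_per_level = as.integer(iterations_per_level),
                 seed = as.integer(seed)),
            class = "cg_placement_params")
}

## ---- operation reports ----------------------------------------------------

cg_report <- function(operation, subject,
                      created_meta_edges = character(),
                      discarded_meta_edges = character(),
                      reconnected_meta_edges = list(),
                      archived_elements = character(),
                      restored_elements = character(),
                      hidden_elements = character(),
                      shown_elements = character(),
                      skipped = character(),
                      levels = list(),
                      layout_iterations = 0L,
                      edge_touch_count = 0L) {
  structure(list(operation = operation, subject = subject,
                 created_meta_edges = created_meta_edges,
                 discarded_meta_edges = discarded_meta_edges,
                 reconnected_meta_edges = reconnected_meta_edges,
                 archived_elements = archived_elements,
                 restored_elements = restored_elements,
                 hidden_elements = hidden_elements,
                 shown_elements = shown_elements,
                 skipped = skipped, levels = levels,
                 layout_iterations = as.integer(layout_iterations),
                 edge_touch_count = as.integer(edge_touch_count)),
            class = "cg_op_report")
}

#' @export
print.cg_op_report <- function(x, ...) {
  cat(sprintf("<op report> %s(%s): +%d meta, -%d meta, %d reconnected, %d archived, %d restored, %d layout iter, %d edge touches\n",
              x$operation, paste(x$subject, collapse = ","),
              length(x$created_meta_edges), length(x$discarded_meta_edges),
              length(x$reconnected_meta_edges), length(x$archived_elements),
              length(x$restored_elements), x$layout_iterations,
              x$edge_touch_count))
  invisible(x)
}

cg_merge_reports <- function(operation, subject, reports) {
  out <- cg_report(operation, subject)
  for (r in reports) {
    for (f in c("created_meta_edges", "discarded_meta_edges", "archived_elements",
                "restored_elements", "hidden_elements", "shown_elements", "skipped"))
      out[[f]] <- c(out[[f]], r[[f]])
    out$reconnected_meta_edges <- c(out$reconnected_meta_edges, r$reconnected_meta_edges)
    out$levels <- c(out$levels, r$levels)
    out$layout_iterations <- out$layout_iterations + r$layout_iterations
    out$edge_touch_count <- out$edge_touch_count + r$edge_touch_count
  }
  out
}

## Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
## caller's state afterwards.
cg_with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  expr
}
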