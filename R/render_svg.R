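#' @title SVG renderer with expand/collapse cues
#' @description Draws the visible part of a compound graph: leaf nodes as
#'   rectangles, expanded compounds as enclosing rectangles, edges as lines
#'   (meta edges dashed), and an expand/collapse cue glyph at the top-left
#'   corner of every compound — a plus sign on collapsed nodes, a minus sign
#'   on expanded ones. While a highlight is active, elements outside the
#'   highlighted set are drawn at a reduced opacity. Model space is y-up;
#'   the renderer flips the y axis for screen output.
#' @name render-svg
NULL

#' Rendering style
#'
#' @param cue_size side length of the cue glyph (default 12).
#' @param cue_line_size stroke width of the cue glyph lines (default 8).
#' @param cue_position only `"top-left"` is supported.
#' @param unhighlighted_opacity opacity for elements outside an active
#'   highlight (default 0.3).
#' @param meta_edge_dash SVG dash pattern for meta edges.
#' @param compound_fill fill colour of expanded compound rectangles.
#' @return a list of class `cg_render_style`.
#' @export
render_style <- function(cue_size = 12, cue_line_size = 8,
                         cue_position = "top-left",
                         unhighlighted_opacity = 0.3,
                         meta_edge_dash = "6,3",
                         compound_fill = "#f0f0f8") {
  stopifnot(cue_size > 0, cue_line_size > 0,
            unhighlighted_opacity >= 0, unhighlighted_opacity <= 1,
            identical(cue_position, "top-left"))
  structure(list(cue_size = cue_size, cue_line_size = cue_line_size,
                 cue_position = cue_position,
                 unhighlighted_opacity = unhighlighted_opacity,
                 meta_edge_dash = meta_edge_dash,
                 compound_fill = compound_fill),
            class = "cg_render_style")
}

#' Render a compound graph to SVG
#'
#' @inheritParams collapse_node
#' @param style a [render_style()] list.
#' @param path output file path.
#' @return a summary list: element counts, cue records (node, type, centre,
#'   geometry) and the number of elements drawn at reduced opacity.
#' @export
render_svg <- function(graph, style = render_style(), path) {
  children <- cg_children_map(graph)
  vis_nodes <- cg_visible_nodes(graph)
  vis_edges <- cg_visible_edges(graph)
  dim_active <- graph$highlight_active

  opacity_of <- function(el) {
    if (dim_active && !el$highlighted) style$unhighlighted_opacity else 1
  }
  dimmed <- 0L

  ## viewport from visible boxes (y flipped for screen space)
  if (length(vis_nodes)) {
    xs <- ys <- numeric(0)
    for (id in vis_nodes) {
      nd <- graph$nodes[[id]]
      xs <- c(xs, nd$x - nd$width / 2, nd$x + nd$width / 2)
      ys <- c(ys, -nd$y - nd$height / 2, -nd$y + nd$height / 2)
    }
    pad <- 20
    vb <- c(min(xs) - pad, min(ys) - pad,
            diff(range(xs)) + 2 * pad, diff(range(ys)) + 2 * pad)
  } else vb <- c(0, 0, 100, 100)

  out <- sprintf(
    '<svg xmlns="http://www.w3.org/2000/svg" viewBox="%s %s %s %s">',
    cg_num(vb[1]), cg_num(vb[2]), cg_num(vb[3]), cg_num(vb[4]))

  is_compound <- vapply(vis_nodes, function(i) cg_is_compound(graph, i, children),
                        logical(1))
  compounds <- vis_nodes[is_compound]
  leaves <- vis_nodes[!is_compound]

  ## expanded compounds behind everything, outermost first
  expanded <- compounds[!vapply(compounds, function(i) graph$nodes[[i]]$collapsed,
                                logical(1))]
  expanded <- expanded[order(vapply(expanded, function(i)
    inclusion_level(graph, i), integer(1)))]
  for (id in expanded) {
    nd <- graph$nodes[[id]]
    op <- opacity_of(nd); if (op < 1) dimmed <- dimmed + 1L
    out <- c(out, sprintf(
      '  <rect class="compound" id="%s" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#666" opacity="%s"/>',
      cg_xml_escape(id), cg_num(nd$x - nd$width / 2), cg_num(-nd$y - nd$height / 2),
      cg_num(nd$width), cg_num(nd$height), style$compound_fill, cg_num(op)))
  }

  meta_drawn <- 0L
  for (eid in sort(vis_edges)) {
    ed <- graph$edges[[eid]]
    a <- graph$nodes[[ed$source]]; b <- graph$nodes[[ed$target]]
    op <- opacity_of(ed); if (op < 1) dimmed <- dimmed + 1L
    dash <- if (ed$kind == "meta") sprintf(' stroke-dasharray="%s"', style$meta_edge_dash) else ""
    if (ed$kind == "meta") meta_drawn <- meta_drawn + 1L
    out <- c(out, sprintf(
      '  <line class="edge %s" id="%s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#333" opacity="%s"%s/>',
      ed$kind, cg_xml_escape(eid), cg_num(a$x), cg_num(-a$y),
      cg_num(b$x), cg_num(-b$y), cg_num(op), dash))
  }

  for (id in sort(c(leaves, compounds[vapply(compounds, function(i)
    graph$nodes[[i]]$collapsed, logical(1))]))) {
    nd <- graph$nodes[[id]]
    op <- opacity_of(nd); if (op < 1) dimmed <- dimmed + 1L
    out <- c(out, sprintf(
      '  <rect class="node" id="%s" x="%s" y="%s" width="%s" height="%s" fill="#cfe2ff" stroke="#335" opacity="%s"/>',
      cg_xml_escape(id), cg_num(nd$x - nd$width / 2), cg_num(-nd$y - nd$height / 2),
      cg_num(nd$width), cg_num(nd$height), cg_num(op)))
  }

  ## cues: plus on collapsed compounds, minus on expanded ones
  cues <- list()
  for (id in sort(compounds)) {
    nd <- graph$nodes[[id]]
    cs <- style$cue_size
    cx <- nd$x - nd$width / 2 + cs / 2
    cy <- -nd$y - nd$height / 2 + cs / 2
    type <- if (nd$collapsed) "plus" else "minus"
    out <- c(out, sprintf(
      '  <line class="cue %s" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000" stroke-width="%s"/>',
      type, cg_num(cx - cs / 2), cg_num(cy), cg_num(cx + cs / 2), cg_num(cy),
      cg_num(style$cue_line_size)))
    if (nd$collapsed)
      out <- c(out, sprintf(
        '  <line class="cue plus" x1="%s" y1="%s" x2="%s" y2="%s" stroke="#000" stroke-width="%s"/>',
        cg_num(cx), cg_num(cy - cs / 2), cg_num(cx), cg_num(cy + cs / 2),
        cg_num(style$cue_line_size)))
    cues[[length(cues) + 1L]] <- list(node = id, type = type, x = cx, y = cy,
                                      size = cs, line_size = style$cue_line_size)
  }
  out <- c(out, "</svg>")
  writeLines(out, path)
  list(nodes_drawn = length(leaves) + sum(vapply(compounds, function(i)
         graph$nodes[[i]]$collapsed, logical(1))),
       compounds_drawn = length(expanded),
       edges_drawn = length(vis_edges),
       meta_edges_drawn = meta_drawn,
       cues = cues,
       dimmed_elements = dimmed,
       path = path)
}
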