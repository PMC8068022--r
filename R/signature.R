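# Tactile-signature opposition graph: per-task region CGF rendered as
# proportional circles on a schematic hand, with lines connecting finger
# regions to opposing thumb or palm regions when both contribute more than a
# threshold (5% by default) of the grip force.

#' Build the opposition signature graph for one task
#'
#' Nodes are the 18 regions with radius linearly proportional to their mean
#' CGF. An edge joins a finger-class region (3-14) to a thumb- (1-2) or
#' palm-class (15-18) region iff both CGFs exceed the threshold; finger-finger,
#' thumb-palm and palm-palm pairs are never connected.
#'
#' @param mean_cgf Length-18 vector of fractions summing to 1 (within 1e-6).
#' @param layout A `sensor_layout` (render coordinates and classes).
#' @param threshold Edge threshold as a CGF fraction, default 0.05.
#' @return A `signature_graph`: list with `nodes` (data.frame: region, cgf,
#'   radius, x, y, class), `edges` (data.frame: finger, opposing) and
#'   `threshold`.
#' @export
build_signature <- function(mean_cgf, layout, threshold = 0.05) {
  if (length(mean_cgf) != 18)
    stop("mean_cgf must have length 18, got ", length(mean_cgf))
  if (abs(sum(mean_cgf) - 1) > 1e-6)
    stop("mean_cgf must sum to 1, got ", sum(mean_cgf))
  reg <- layout$regions[order(layout$regions$id), ]
  nodes <- data.frame(region = reg$id, cgf = as.numeric(mean_cgf),
                      radius = as.numeric(mean_cgf),
                      x = reg$x, y = reg$y, class = reg$class,
                      stringsAsFactors = FALSE)
  hot <- which(mean_cgf > threshold)
  fingers <- intersect(hot, which(nodes$class == "finger"))
  opposing <- intersect(hot, which(nodes$class %in% c("thumb", "palm")))
  edges <- expand.grid(finger = fingers, opposing = opposing)
  edges <- edges[order(edges$finger, edges$opposing), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, threshold = threshold),
            class = "signature_graph")
}

#' @export
print.signature_graph <- function(x, ...) {
  cat(sprintf("<signature_graph> %d regions, %d opposition edges (CGF > %g%%)\n",
              nrow(x$nodes), nrow(x$edges), 100 * x$threshold))
  invisible(x)
}

#' Render a signature graph as an SVG file
#'
#' Writes a deterministic standalone SVG: opposition lines underneath, one
#' circle per region with radius proportional to CGF, and region-id labels.
#' Identical graphs render to byte-identical files.
#'
#' @param graph A `signature_graph`.
#' @param path Output file path (`.svg`).
#' @param max_radius Radius in px of a (hypothetical) CGF = 1 region scaled
#'   down by 1/0.35; default gives readable circles for typical CGFs <= 0.35.
#' @return `path`, invisibly.
#' @export
render_signature <- function(graph, path, max_radius = 90) {
  stopifnot(inherits(graph, "signature_graph"))
  dir <- dirname(path)
  if (!dir.exists(dir) || file.access(dir, mode = 2) != 0)
    stop("cannot write to ", dir)
  n <- graph$nodes
  # map abstract hand frame to a 400x440 viewport, y up
  px <- function(x) 40 + x * 45
  py <- function(y) 420 - y * 45
  r_px <- function(cgf) cgf / 0.35 * max_radius * 0.35
  fmt <- function(v) sprintf("%.3f", v)
  lines <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<svg xmlns="http://www.w3.org/2000/svg" width="400" height="440" viewBox="0 0 400 440">',
    '<rect width="400" height="440" fill="white"/>')
  if (nrow(graph$edges))
    for (i in seq_len(nrow(graph$edges))) {
      a <- n[graph$edges$finger[i], ]
      b <- n[graph$edges$opposing[i], ]
      lines <- c(lines, sprintf(
        '<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="#555555" stroke-width="2"/>',
        fmt(px(a$x)), fmt(py(a$y)), fmt(px(b$x)), fmt(py(b$y))))
    }
  fill <- c(thumb = "#d95f02", finger = "#1b9e77", palm = "#7570b3")
  for (i in seq_len(nrow(n))) {
    lines <- c(lines, sprintf(
      '<circle cx="%s" cy="%s" r="%s" fill="%s" fill-opacity="0.7" stroke="black"/>',
      fmt(px(n$x[i])), fmt(py(n$y[i])), fmt(max(r_px(n$cgf[i]), 0.5)),
      fill[[n$class[i]]]))
    lines <- c(lines, sprintf(
      '<text x="%s" y="%s" font-size="10" text-anchor="middle">%d</text>',
      fmt(px(n$x[i])), fmt(py(n$y[i]) - 3), n$region[i]))
  }
  lines <- c(lines, "</svg>")
  writeLines(lines, path)
  invisible(path)
}
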