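#' Rendering specification for SOM mosaic images
#'
#' The default color scale runs blue over green to red (low to high);
#' inversion reverses it (used for the segment length map so small values
#' read warm). Masked nodes render in the mask color (white).
#'
#' @param palette color ramp anchors, low to high.
#' @param scale `"linear"` or `"log"`.
#' @param inverted reverse the ramp.
#' @param limits explicit `c(min, max)` or `NULL` for auto.
#' @param mask_color color for masked (`NA`) nodes.
#' @param border_color color for island border overlay.
#' @return object of class `render_spec`.
#' @export
render_spec <- function(palette = c("blue", "green", "red"),
                        scale = c("linear", "log"), inverted = FALSE,
                        limits = NULL, mask_color = "white",
                        border_color = "black") {
  scale <- match.arg(scale)
  if (!is.null(limits)) {
    stopifnot(length(limits) == 2)
    if (limits[1] >= limits[2]) stop("render_spec: need min < max")
  }
  structure(list(palette = palette, scale = scale,
                 inverted = isTRUE(inverted), limits = limits,
                 mask_color = mask_color, border_color = border_color),
            class = "render_spec")
}

# log transform used for rendering: log10(v + 1) when zeros are present
# (count-like maps), plain log10 for strictly positive maps
.render_transform <- function(values, scale) {
  if (scale != "log") return(values)
  v <- values[!is.na(values)]
  if (any(v < 0))
    stop("map_colors: validation error: log scale with negative values")
  if (any(v == 0)) log10(values + 1) else log10(values)
}

#' Map node values to colors (pure function)
#'
#' Equal values give equal colors; strictly larger values give colors
#' strictly later in the (un-inverted) ramp. `NA` gives the mask color.
#'
#' @param values numeric vector (`NA` = masked).
#' @param spec a [render_spec()].
#' @return character vector of hex colors.
#' @export
map_colors <- function(values, spec = render_spec()) {
  v <- .render_transform(values, spec$scale)
  lim <- spec$limits
  if (!is.null(lim)) lim <- .render_transform(lim, spec$scale)
  ok <- !is.na(v)
  out <- rep(spec$mask_color, length(v))
  if (!any(ok)) return(out)
  if (is.null(lim)) lim <- range(v[ok])
  t <- if (lim[2] > lim[1]) (pmin(pmax(v[ok], lim[1]), lim[2]) - lim[1]) /
    (lim[2] - lim[1]) else rep(0.5, sum(ok))
  if (spec$inverted) t <- 1 - t
  ramp <- grDevices::colorRamp(spec$palette, space = "Lab")
  rgb <- ramp(t)
  out[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  out
}

#' Render a node map as a mosaic (SOM-image)
#'
#' One tile per node at its grid position; masked nodes in the mask color;
#' optionally overlays island borders (nodes below the occupancy threshold)
#' in the border color.
#'
#' @param map a [node_map()].
#' @param spec a [render_spec()]; by default inherits the map's scale and
#'   inverted hints.
#' @param path output PNG path.
#' @param islands optional [island_labeling()]; border (non-island) nodes
#'   are drawn in `spec$border_color`.
#' @param tile_px pixels per tile.
#' @return `path`, invisibly.
#' @export
render_heatmap <- function(map, spec = NULL, path, islands = NULL,
                           tile_px = 12) {
  if (is.null(spec))
    spec <- render_spec(scale = map$scale, inverted = map$inverted)
  cols <- map_colors(map$values, spec)
  if (!is.null(islands))
    cols[is.na(islands$node_island)] <- spec$border_color
  w <- map$width; h <- map$height
  grDevices::png(path, width = w * tile_px, height = h * tile_px)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() }, add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(h, 0), xaxs = "i",
                        yaxs = "i")
  k <- seq_len(w * h)
  col_i <- (k - 1L) %% w
  row_i <- (k - 1L) %/% w
  graphics::rect(col_i, row_i + 1, col_i + 1, row_i, col = cols,
                 border = NA)
  invisible(path)
}
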