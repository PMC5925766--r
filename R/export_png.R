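#' Export a figure as a static PNG image
#'
#' Renders the same layout as [to_html()] (identical geometry: the two share
#' one display list) onto the `grDevices` PNG device at the requested pixel
#' dimensions.
#'
#' @param fig An `interheat_figure` from [build_figure()].
#' @param path Output path (conventionally `.png`).
#' @param width_px,height_px Image dimensions in pixels.
#' @return `path`, invisibly.
#' @export
to_png <- function(fig, path, width_px = 900, height_px = 700) {
  stopifnot(inherits(fig, "interheat_figure"))
  if (width_px < 1 || height_px < 1) {
    stop("width_px and height_px must be positive", call. = FALSE)
  }
  if (!capabilities("png")) {
    stop("PNG export needs R compiled with libpng support ",
         "(capabilities(\"png\") must be TRUE); rebuild or reinstall R ",
         "with png support enabled", call. = FALSE)
  }
  prim <- .figure_primitives(fig)
  grDevices::png(path, width = width_px, height = height_px)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
  graphics::plot.new()
  # figure coordinates: y down, preserve the display list's aspect ratio by
  # letterboxing into the device
  asp_fig <- prim$width / prim$height
  asp_dev <- width_px / height_px
  if (asp_dev >= asp_fig) {
    w <- prim$height * asp_dev
    graphics::plot.window(xlim = c(-(w - prim$width) / 2,
                                   prim$width + (w - prim$width) / 2),
                          ylim = c(prim$height, 0))
  } else {
    h <- prim$width / asp_dev
    graphics::plot.window(xlim = c(0, prim$width),
                          ylim = c(prim$height + (h - prim$height) / 2,
                                   -(h - prim$height) / 2))
  }
  graphics::rect(0, prim$height, prim$width, 0, col = "#FFFFFF",
                 border = NA)
  for (r in prim$rects) {
    graphics::rect(r$x, r$y + r$h, r$x + r$w, r$y, col = r$fill, border = NA)
  }
  for (l in prim$lines) {
    graphics::segments(l$x0, l$y0, l$x1, l$y1, col = l$color, lwd = 1.5)
  }
  scale_px <- min(width_px / prim$width, height_px / prim$height)
  for (t in prim$texts) {
    adj <- switch(t$anchor, start = 0, middle = 0.5, end = 1)
    graphics::text(t$x, t$y, labels = t$str, adj = c(adj, 0),
                   srt = -t$rot, cex = t$size / 12 * scale_px * 1.4)
  }
  invisible(path)
}
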