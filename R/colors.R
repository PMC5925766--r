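# Palette stop tables, 11 fixed stops each, frozen as constants so output is
# byte-reproducible. Sources: viridis — viridisLite::viridis(11);
# cool_warm — Moreland's smooth cool-warm diverging map sampled at 11 points
# (matplotlib's "coolwarm"); rdbu/brbg/rdylbu — ColorBrewer 11-class schemes
# (RColorBrewer), oriented low -> high.
.palettes <- list(
  viridis = c("#440154", "#482576", "#414487", "#35608D", "#2A788E",
              "#21908C", "#22A884", "#43BF71", "#7AD151", "#BBDF27",
              "#FDE725"),
  cool_warm = c("#3B4CC0", "#5977E3", "#7B9FF9", "#9EBEFF", "#C0D4F5",
                "#DDDCDC", "#F2CBB7", "#F7AC8E", "#EE8468", "#D65244",
                "#B40426"),
  rdbu = c("#053061", "#2166AC", "#4393C3", "#92C5DE", "#D1E5F0", "#F7F7F7",
           "#FDDBC7", "#F4A582", "#D6604D", "#B2182B", "#67001F"),
  brbg = c("#003C30", "#01665E", "#35978F", "#80CDC1", "#C7EAE5", "#F5F5F5",
           "#F6E8C3", "#DFC27D", "#BF812D", "#8C510A", "#543005"),
  rdylbu = c("#313695", "#4575B4", "#74ADD1", "#ABD9E9", "#E0F3F8", "#FFFFBF",
             "#FEE090", "#FDAE61", "#F46D43", "#D73027", "#A50026")
)
.sequential_palettes <- "viridis"

#' Build a color scale
#'
#' A color scale maps matrix values to colors: a named palette (ordered hex
#' stops at equally spaced positions in \[0, 1\]), explicit or automatic
#' limits, and a color for missing cells. The default sequential palette is
#' viridis — colorful, perceptually ordered (luminance increases
#' monotonically along it) and robust to common color-vision deficiencies.
#' The divergent palettes (cool_warm and the ColorBrewer schemes RdBu, BrBG,
#' RdYlBu) have a neutral midpoint and suit signed quantities.
#'
#' @param palette One of `"viridis"`, `"cool_warm"`, `"rdbu"`, `"brbg"`,
#'   `"rdylbu"`.
#' @param limits Numeric `c(lo, hi)` with `lo < hi`, or `NULL` for automatic
#'   limits (the finite range of the data being drawn).
#' @param na_color Hex color for missing cells.
#' @return An `interheat_scale` list: `kind` (`"sequential"` or
#'   `"divergent"`), `palette`, `stops` (hex colors at positions
#'   `seq(0, 1, length.out = length(stops))`), `limits`, `na_color`.
#' @export
#' @examples
#' color_scale()                            # sequential viridis, auto limits
#' color_scale("cool_warm", limits = c(-1, 1))  # for correlation matrices
color_scale <- function(palette = "viridis", limits = NULL,
                        na_color = "#808080") {
  palette <- match.arg(palette, names(.palettes))
  if (!is.null(limits)) {
    if (length(limits) != 2L || !is.numeric(limits) ||
        !(limits[1L] < limits[2L])) {
      stop("limits must be numeric c(lo, hi) with lo < hi", call. = FALSE)
    }
    limits <- as.numeric(limits)
  }
  structure(list(
    kind = if (palette %in% .sequential_palettes) "sequential"
           else "divergent",
    palette = palette,
    stops = .palettes[[palette]],
    limits = limits,
    na_color = toupper(na_color)
  ), class = "interheat_scale")
}

#' Default scale for a data kind
#'
#' Plain magnitude data get the sequential viridis scale with automatic
#' limits; correlation matrices get the divergent cool_warm scale with limits
#' fixed at \[-1, 1\], so that the neutral midpoint sits exactly at zero
#' correlation and the two ends are visually distinct.
#'
#' @param data_kind `"plain"` or `"correlation"`.
#' @return An `interheat_scale`.
#' @export
pick_default_scale <- function(data_kind = c("plain", "correlation")) {
  data_kind <- match.arg(data_kind)
  if (data_kind == "correlation") {
    color_scale("cool_warm", limits = c(-1, 1))
  } else {
    color_scale("viridis")
  }
}

#' Map values to colors under a scale
#'
#' Values are clamped to the scale limits, mapped to a position
#' `p = (v - lo) / (hi - lo)` and colored by piecewise-linear interpolation
#' in RGB between the bracketing palette stops. Missing values get the
#' scale's `na_color`.
#'
#' @param scale An `interheat_scale` (see [color_scale()]).
#' @param v Numeric vector (may contain `NA`).
#' @param limits Fallback limits when the scale's are automatic; defaults to
#'   the finite range of `v`.
#' @return Character vector of upper-case `#RRGGBB` hex colors.
#' @export
value_to_color <- function(scale, v, limits = NULL) {
  stopifnot(inherits(scale, "interheat_scale"))
  lims <- scale$limits %||% limits %||% range(v, na.rm = TRUE, finite = TRUE)
  if (!is.finite(lims[1L]) || !is.finite(lims[2L])) lims <- c(0, 1)
  if (lims[1L] == lims[2L]) lims <- lims + c(-0.5, 0.5)
  p <- (pmin(pmax(v, lims[1L]), lims[2L]) - lims[1L]) / (lims[2L] - lims[1L])
  out <- rep(scale$na_color, length(v))
  ok <- !is.na(p)
  out[ok] <- .interp_hex(scale$stops, p[ok])
  out
}

# Piecewise-linear RGB interpolation along equally spaced stops.
.interp_hex <- function(stops, p) {
  rgb_stops <- t(grDevices::col2rgb(stops))          # k x 3
  k <- length(stops)
  x <- p * (k - 1L)
  lo <- pmin(floor(x), k - 2L)                       # bracketing stop index
  frac <- x - lo
  chan <- rgb_stops[lo + 1L, , drop = FALSE] * (1 - frac) +
          rgb_stops[lo + 2L, , drop = FALSE] * frac
  chan <- round(chan)
  toupper(grDevices::rgb(chan[, 1L], chan[, 2L], chan[, 3L],
                         maxColorValue = 255))
}

#' Distinct categorical colors for cluster branches and annotations
#'
#' Deterministic set of `k` maximally separated hues at fixed chroma and
#' luminance (HCL space), used to color dendrogram branches by cluster and
#' annotation sidebar categories. Colors are assigned to clusters in order
#' of first appearance along the leaf order.
#'
#' @param k Number of colors, `k >= 1`.
#' @return Character vector of `k` distinct `#RRGGBB` colors.
#' @export
cluster_colors <- function(k) {
  stopifnot(k >= 1L)
  hues <- seq(15, 375, length.out = k + 1L)[seq_len(k)]
  toupper(substr(grDevices::hcl(h = hues, c = 85, l = 60), 1L, 7L))
}

#' Relative luminance of colors
#'
#' WCAG relative luminance (linearized sRGB, Rec. 709 weights); used to
#' verify that sequential palettes are monotone in lightness.
#'
#' @param colors Character vector of hex colors.
#' @return Numeric vector in `[0, 1]`.
#' @export
relative_luminance <- function(colors) {
  rgb01 <- t(grDevices::col2rgb(colors)) / 255
  lin <- ifelse(rgb01 <= 0.04045, rgb01 / 12.92,
                ((rgb01 + 0.055) / 1.055)^2.4)
  as.numeric(lin %*% c(0.2126, 0.7152, 0.0722))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
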