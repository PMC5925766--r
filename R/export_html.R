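# Shared figure geometry. Both exporters consume the same display list of
# primitives, so the HTML and PNG depict the identical layout.
#
# Primitive records:
#   rect: x, y, w, h, fill, tip (tooltip HTML or NA)
#   line: x0, y0, x1, y1, color
#   text: x, y, str, size, anchor ("start"|"middle"|"end"), rot (0 or 90)
# Coordinates: y grows downward, origin top-left, units = CSS px.
.figure_primitives <- function(fig) {
  m <- fig$values
  nr <- nrow(m); nc <- ncol(m)
  cw <- 22; ch <- 18
  pad <- 10
  frac <- fig$cfg$dendrogram_fraction
  title_h <- if (nzchar(fig$cfg$figure_title)) 34 else 0
  dend_w <- if (!is.null(fig$row_tree)) max(60, round(frac * nc * cw)) else 0
  dend_h <- if (!is.null(fig$col_tree)) max(60, round(frac * nr * ch)) else 0

  row_ann <- Filter(function(a) a$axis == "row", fig$annotations)
  col_ann <- Filter(function(a) a$axis == "column", fig$annotations)
  ann_w <- if (length(row_ann)) length(row_ann) * 18 else 0
  ann_h <- if (length(col_ann)) length(col_ann) * 18 else 0

  rl_w <- if (fig$cfg$show_row_labels)
    max(nchar(rownames(m))) * 7 + 8 else 4
  cl_h <- if (fig$cfg$show_col_labels)
    max(nchar(colnames(m))) * 7 + 8 else 4
  cbar_w <- 66

  hx <- pad + dend_w + ann_w      # heatmap top-left
  hy <- pad + title_h + dend_h + ann_h
  W <- hx + nc * cw + rl_w + cbar_w + pad
  legend_h <- if (length(fig$annotations)) 22 * length(fig$annotations) + 8
              else 0
  H <- hy + nr * ch + cl_h + legend_h + pad

  rects <- list(); lines <- list(); texts <- list()
  add_rect <- function(...) rects[[length(rects) + 1L]] <<- list(...)
  add_line <- function(...) lines[[length(lines) + 1L]] <<- list(...)
  add_text <- function(...) texts[[length(texts) + 1L]] <<- list(...)

  if (nzchar(fig$cfg$figure_title)) {
    add_text(x = W / 2, y = pad + 18, str = fig$cfg$figure_title, size = 16,
             anchor = "middle", rot = 0)
  }

  # heatmap cells (row 1 at the top)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      add_rect(x = hx + (j - 1) * cw, y = hy + (i - 1) * ch, w = cw, h = ch,
               fill = fig$cell_colors[i, j], tip = fig$tooltips[i, j])
    }
  }

  # row dendrogram, left of the heatmap, height growing leftward
  if (!is.null(fig$row_dendrogram)) {
    seg <- fig$row_dendrogram
    hmax <- max(seg$y1, seg$y0, 1e-12)
    sx <- function(h) pad + dend_w * (1 - h / hmax)       # height -> x
    sy <- function(leaf_pos) hy + leaf_pos * ch           # leaf axis -> y
    for (r in seq_len(nrow(seg))) {
      add_line(x0 = sx(seg$y0[r]), y0 = sy(seg$x0[r]),
               x1 = sx(seg$y1[r]), y1 = sy(seg$x1[r]), color = seg$color[r])
    }
  }

  # column dendrogram, above the heatmap, height growing upward
  if (!is.null(fig$col_dendrogram)) {
    seg <- fig$col_dendrogram
    hmax <- max(seg$y1, seg$y0, 1e-12)
    top <- pad + title_h
    sy2 <- function(h) top + dend_h * (1 - h / hmax)
    sx2 <- function(leaf_pos) hx + leaf_pos * cw
    for (r in seq_len(nrow(seg))) {
      add_line(x0 = sx2(seg$x0[r]), y0 = sy2(seg$y0[r]),
               x1 = sx2(seg$x1[r]), y1 = sy2(seg$y1[r]), color = seg$color[r])
    }
  }

  # annotation sidebars
  ann_palette <- function(track) {
    stats::setNames(cluster_colors(length(track$level_order)),
                    track$level_order)
  }
  for (t in seq_along(row_ann)) {
    track <- row_ann[[t]]
    colors <- ann_palette(track)[track$categories]
    x <- pad + dend_w + (t - 1) * 18
    for (i in seq_len(nr)) {
      add_rect(x = x, y = hy + (i - 1) * ch, w = 14, h = ch,
               fill = unname(colors[i]),
               tip = paste0(.html_escape(track$name), ": ",
                            .html_escape(track$categories[i])))
    }
  }
  for (t in seq_along(col_ann)) {
    track <- col_ann[[t]]
    colors <- ann_palette(track)[track$categories]
    y <- pad + title_h + dend_h + (t - 1) * 18
    for (j in seq_len(nc)) {
      add_rect(x = hx + (j - 1) * cw, y = y, w = cw, h = 14,
               fill = unname(colors[j]),
               tip = paste0(.html_escape(track$name), ": ",
                            .html_escape(track$categories[j])))
    }
  }

  # axis labels
  if (fig$cfg$show_row_labels) {
    for (i in seq_len(nr)) {
      add_text(x = hx + nc * cw + 6, y = hy + (i - 0.5) * ch + 4,
               str = rownames(m)[i], size = 11, anchor = "start", rot = 0)
    }
  }
  if (fig$cfg$show_col_labels) {
    for (j in seq_len(nc)) {
      add_text(x = hx + (j - 0.5) * cw + 4, y = hy + nr * ch + 6,
               str = colnames(m)[j], size = 11, anchor = "end", rot = 90)
    }
  }

  # colorbar
  cb_x <- hx + nc * cw + rl_w + 6
  cb_y <- hy
  cb_h <- max(nr * ch, 60)
  nstop <- 64
  for (s in seq_len(nstop)) {
    v <- fig$limits[2] - (s - 0.5) / nstop * diff(fig$limits)
    add_rect(x = cb_x, y = cb_y + (s - 1) * cb_h / nstop, w = 16,
             h = cb_h / nstop + 0.5,
             fill = value_to_color(fig$scale, v, limits = fig$limits),
             tip = NA)
  }
  add_text(x = cb_x + 20, y = cb_y + 10, str = .fmt_val(fig$limits[2]),
           size = 10, anchor = "start", rot = 0)
  add_text(x = cb_x + 20, y = cb_y + cb_h, str = .fmt_val(fig$limits[1]),
           size = 10, anchor = "start", rot = 0)
  add_text(x = cb_x + 8, y = cb_y - 6, str = fig$cfg$scale_name, size = 11,
           anchor = "start", rot = 0)

  # annotation legends
  if (length(fig$annotations)) {
    ly <- hy + nr * ch + cl_h + 16
    for (track in fig$annotations) {
      colors <- ann_palette(track)
      add_text(x = pad, y = ly, str = paste0(track$name, ":"), size = 11,
               anchor = "start", rot = 0)
      lx <- pad + nchar(track$name) * 7 + 14
      for (lev in track$level_order) {
        add_rect(x = lx, y = ly - 10, w = 12, h = 12,
                 fill = unname(colors[lev]), tip = NA)
        add_text(x = lx + 16, y = ly, str = lev, size = 11,
                 anchor = "start", rot = 0)
        lx <- lx + 24 + nchar(lev) * 7
      }
      ly <- ly + 22
    }
  }

  list(width = W, height = H, rects = rects, lines = lines, texts = texts)
}

.fmt_val <- function(v) format(signif(v, 4))

.html_escape <- function(s) {
  s <- gsub("&", "&amp;", s, fixed = TRUE)
  s <- gsub("<", "&lt;", s, fixed = TRUE)
  s <- gsub(">", "&gt;", s, fixed = TRUE)
  gsub("\"", "&quot;", s, fixed = TRUE)
}

.num <- function(x) {
  out <- formatC(x, format = "f", digits = 2)
  sub("\\.?0+$", "", out)
}

#' Export a figure as a standalone interactive HTML file
#'
#' Writes a single self-contained HTML file: the figure is an inline SVG and
#' the interactivity (hover tooltips on every cell, mouse-wheel zoom, drag
#' pan, double-click reset) is a small embedded script. The file references
#' no external resource, so it can be opened offline, mailed, or uploaded as
#' supplementary material. Output is byte-deterministic: the same bundle
#' always serializes to the identical file.
#'
#' @param fig An `interheat_figure` from [build_figure()].
#' @param path Output path (conventionally `.html`).
#' @return `path`, invisibly.
#' @export
to_html <- function(fig, path) {
  stopifnot(inherits(fig, "interheat_figure"))
  prim <- .figure_primitives(fig)

  svg <- c(
    sprintf(paste0('<svg id="ih-svg" xmlns="http://www.w3.org/2000/svg" ',
                   'viewBox="0 0 %s %s" width="%s" height="%s" ',
                   'font-family="Helvetica,Arial,sans-serif">'),
            .num(prim$width), .num(prim$height),
            .num(prim$width), .num(prim$height)),
    sprintf('<rect x="0" y="0" width="%s" height="%s" fill="#FFFFFF"/>',
            .num(prim$width), .num(prim$height)),
    vapply(prim$rects, function(r) {
      tip_attr <- if (is.na(r$tip)) "" else
        sprintf(' class="ih-cell" data-tip="%s"', .html_escape(r$tip))
      sprintf('<rect x="%s" y="%s" width="%s" height="%s" fill="%s"%s/>',
              .num(r$x), .num(r$y), .num(r$w), .num(r$h), r$fill, tip_attr)
    }, character(1)),
    vapply(prim$lines, function(l) {
      sprintf(paste0('<line x1="%s" y1="%s" x2="%s" y2="%s" stroke="%s" ',
                     'stroke-width="1.5"/>'),
              .num(l$x0), .num(l$y0), .num(l$x1), .num(l$y1), l$color)
    }, character(1)),
    vapply(prim$texts, function(t) {
      transform <- if (t$rot != 0)
        sprintf(' transform="rotate(%s %s %s)"', .num(t$rot),
                .num(t$x), .num(t$y)) else ""
      sprintf(paste0('<text x="%s" y="%s" font-size="%s" ',
                     'text-anchor="%s"%s>%s</text>'),
              .num(t$x), .num(t$y), .num(t$size), t$anchor, transform,
              .html_escape(t$str))
    }, character(1)),
    '</svg>'
  )

  html <- c(
    "<!DOCTYPE html>",
    '<html lang="en">',
    "<head>",
    '<meta charset="utf-8"/>',
    sprintf("<title>%s</title>",
            .html_escape(if (nzchar(fig$cfg$figure_title))
              fig$cfg$figure_title else "interheat figure")),
    "<style>",
    "body{margin:0;background:#FFFFFF}",
    "#ih-wrap{position:relative;display:inline-block}",
    paste0("#ih-tip{position:fixed;display:none;pointer-events:none;",
           "background:rgba(40,40,40,0.92);color:#fff;padding:6px 8px;",
           "border-radius:4px;font:12px Helvetica,Arial,sans-serif;",
           "z-index:10}"),
    "#ih-svg{cursor:crosshair}",
    "</style>",
    "</head>",
    "<body>",
    '<div id="ih-wrap">',
    svg,
    '<div id="ih-tip"></div>',
    "</div>",
    "<script>",
    .viewer_js(),
    "</script>",
    "</body>",
    "</html>"
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(html, con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

# Inline viewer: tooltip on hover, wheel zoom about the pointer, drag pan,
# double-click reset. Plain DOM APIs only; nothing is fetched.
.viewer_js <- function() {
  c(
    'var svg=document.getElementById("ih-svg");',
    'var tip=document.getElementById("ih-tip");',
    "var vb0=svg.getAttribute(\"viewBox\").split(\" \").map(Number);",
    "var vb=vb0.slice();",
    'function setVB(){svg.setAttribute("viewBox",vb.join(" "));}',
    "svg.addEventListener(\"mousemove\",function(e){",
    '  var t=e.target.closest(".ih-cell");',
    "  if(t){",
    '    tip.innerHTML=t.getAttribute("data-tip");',
    '    tip.style.display="block";',
    '    tip.style.left=(e.clientX+12)+"px";',
    '    tip.style.top=(e.clientY+12)+"px";',
    '  } else {tip.style.display="none";}',
    "});",
    'svg.addEventListener("mouseleave",function(){tip.style.display="none";});',
    "function toUser(e){",
    "  var r=svg.getBoundingClientRect();",
    "  return [vb[0]+(e.clientX-r.left)/r.width*vb[2],",
    "          vb[1]+(e.clientY-r.top)/r.height*vb[3]];",
    "}",
    "svg.addEventListener(\"wheel\",function(e){",
    "  e.preventDefault();",
    "  var f=e.deltaY<0?0.8:1.25;",
    "  var p=toUser(e);",
    "  vb[0]=p[0]-(p[0]-vb[0])*f; vb[1]=p[1]-(p[1]-vb[1])*f;",
    "  vb[2]*=f; vb[3]*=f; setVB();",
    "},{passive:false});",
    "var drag=null;",
    'svg.addEventListener("pointerdown",function(e){drag=toUser(e);});',
    'window.addEventListener("pointerup",function(){drag=null;});',
    "svg.addEventListener(\"pointermove\",function(e){",
    "  if(!drag)return;",
    "  var p=toUser(e);",
    "  vb[0]-=p[0]-drag[0]; vb[1]-=p[1]-drag[1]; setVB();",
    "});",
    'svg.addEventListener("dblclick",function(){vb=vb0.slice();setVB();});'
  )
}
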