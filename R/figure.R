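#' Layout options for a cluster-heatmap figure
#'
#' @param figure_title Title drawn above the figure (empty for none).
#' @param tooltip_template Template for per-cell hover text; the
#'   placeholders `{row}`, `{col}` and `{value}` are substituted per cell.
#'   Values are formatted to 6 significant digits; missing cells show `NA`.
#' @param scale_name Label for the colorbar (usually the transform name).
#' @param dendrogram_fraction Fraction of the panel devoted to each
#'   dendrogram, strictly between 0 and 0.5.
#' @param show_row_labels,show_col_labels Draw axis labels.
#' @return An `interheat_layout` list.
#' @export
layout_config <- function(figure_title = "",
                          tooltip_template =
                            "row: {row}<br>column: {col}<br>value: {value}",
                          scale_name = "value",
                          dendrogram_fraction = 0.2,
                          show_row_labels = TRUE,
                          show_col_labels = TRUE) {
  if (!(dendrogram_fraction > 0 && dendrogram_fraction < 0.5)) {
    stop("dendrogram_fraction must be in (0, 0.5)", call. = FALSE)
  }
  structure(list(figure_title = figure_title,
                 tooltip_template = tooltip_template,
                 scale_name = scale_name,
                 dendrogram_fraction = dendrogram_fraction,
                 show_row_labels = show_row_labels,
                 show_col_labels = show_col_labels),
            class = "interheat_layout")
}

#' Assemble a cluster-heatmap figure
#'
#' Combines the (already permuted) data matrix, optional row/column
#' dendrograms, optional cluster assignments (which color the dendrogram
#' branches), categorical annotation sidebars and a color scale into a
#' figure bundle that [to_html()] and [to_png()] can export. The matrix is
#' displayed with row 1 at the top, reading order; dendrogram heights grow
#' away from the heatmap.
#'
#' The matrix must already be permuted to the trees' leaf orders (see
#' [apply_order()]); heatmap row `i` always aligns with row-dendrogram leaf
#' `i`. Branch segments at or below a cluster's root are drawn in that
#' cluster's color; segments above any single cluster are neutral grey.
#'
#' @param m Numeric matrix, permuted to leaf orders.
#' @param row_tree,col_tree [stats::hclust] trees whose leaf order matches
#'   the matrix axis, or `NULL` for no dendrogram on that axis.
#' @param row_clusters,col_clusters `interheat_clusters` from [cut_tree()] /
#'   [find_k()], or `NULL` for uncolored branches.
#' @param annotations List of `interheat_annotation` tracks (row and/or
#'   column; see [annotation_track()]), aligned to the permuted matrix.
#' @param scale An `interheat_scale`; automatic limits resolve to the finite
#'   range of `m`.
#' @param cfg An `interheat_layout` from [layout_config()].
#' @return An `interheat_figure` bundle.
#' @export
build_figure <- function(m, row_tree = NULL, col_tree = NULL,
                         row_clusters = NULL, col_clusters = NULL,
                         annotations = list(), scale = color_scale(),
                         cfg = layout_config()) {
  m <- validate_matrix(m)
  stopifnot(inherits(scale, "interheat_scale"),
            inherits(cfg, "interheat_layout"))
  .check_tree_alignment(row_tree, rownames(m), "row")
  .check_tree_alignment(col_tree, colnames(m), "column")

  limits <- scale$limits %||% .finite_range(m)
  cell_colors <- matrix(value_to_color(scale, as.vector(m), limits = limits),
                        nrow = nrow(m), dimnames = dimnames(m))
  tooltips <- .tooltip_matrix(m, cfg$tooltip_template)

  structure(list(
    values = m,
    cell_colors = cell_colors,
    tooltips = tooltips,
    row_tree = row_tree,
    col_tree = col_tree,
    row_dendrogram = if (!is.null(row_tree))
      dendrogram_segments(row_tree, row_clusters),
    col_dendrogram = if (!is.null(col_tree))
      dendrogram_segments(col_tree, col_clusters),
    row_clusters = row_clusters,
    col_clusters = col_clusters,
    annotations = annotations,
    scale = scale,
    limits = limits,
    cfg = cfg
  ), class = "interheat_figure")
}

#' @export
print.interheat_figure <- function(x, ...) {
  cat("interheat figure: ", nrow(x$values), " x ", ncol(x$values),
      " heatmap; row dendrogram: ", !is.null(x$row_tree),
      "; column dendrogram: ", !is.null(x$col_tree), "\n", sep = "")
  invisible(x)
}

.check_tree_alignment <- function(tree, axis_labels, what) {
  if (is.null(tree)) return(invisible())
  stopifnot(inherits(tree, "hclust"))
  tree_labels <- if (is.null(tree$labels)) as.character(seq_along(tree$order))
                 else tree$labels
  if (!identical(tree_labels[tree$order], axis_labels)) {
    stop(what, " dendrogram leaf order does not match the matrix ", what,
         " labels; permute the matrix with apply_order() first",
         call. = FALSE)
  }
  invisible()
}

.finite_range <- function(m) {
  r <- suppressWarnings(range(m, na.rm = TRUE, finite = TRUE))
  if (!all(is.finite(r))) r <- c(0, 1)
  if (r[1L] == r[2L]) r <- r + c(-0.5, 0.5)
  r
}

.tooltip_matrix <- function(m, template) {
  fmt <- function(v) ifelse(is.na(v), "NA",
                            vapply(v, format, character(1), digits = 6))
  out <- matrix("", nrow(m), ncol(m))
  vals <- fmt(m)
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      s <- gsub("{row}", rownames(m)[i], template, fixed = TRUE)
      s <- gsub("{col}", colnames(m)[j], s, fixed = TRUE)
      out[i, j] <- gsub("{value}", vals[i, j], s, fixed = TRUE)
    }
  }
  out
}

#' Line segments of a dendrogram in tree coordinates
#'
#' Converts an [stats::hclust] tree (honoring its current, possibly
#' seriated, leaf order) into drawable segments: leaf `i` in display order
#' sits at position `i - 0.5`, merge nodes at their merge heights. When a
#' cluster assignment is given, every segment lying at or below a cluster's
#' root takes that cluster's color (from [cluster_colors()], indexed by the
#' cluster's first appearance along the leaf order); segments spanning more
#' than one cluster are neutral.
#'
#' @param tree An [stats::hclust] tree.
#' @param clusters Optional `interheat_clusters`.
#' @param neutral Color for segments above the cluster roots.
#' @return A data frame with columns `x0`, `y0`, `x1`, `y1` (x along the
#'   leaf axis, y = merge height) and `color`.
#' @export
dendrogram_segments <- function(tree, clusters = NULL, neutral = "#5A5A5A") {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  leaf_x <- numeric(n)
  leaf_x[tree$order] <- seq_len(n) - 0.5

  cl <- if (!is.null(clusters)) clusters$labels_by_leaf
  pal <- if (!is.null(clusters)) cluster_colors(clusters$k)
  node_cluster <- function(members) {          # cluster id if pure, else NA
    if (is.null(cl)) return(NA_integer_)
    u <- unique(cl[members])
    if (length(u) == 1L) u else NA_integer_
  }
  seg_color <- function(cluster_id) {
    if (is.na(cluster_id)) neutral else pal[cluster_id]
  }

  node_x <- numeric(n - 1L)
  node_members <- vector("list", n - 1L)
  segs <- vector("list", n - 1L)
  for (node in seq_len(n - 1L)) {
    ch <- tree$merge[node, ]
    info <- lapply(ch, function(id) {
      if (id < 0L) {
        list(x = leaf_x[-id], y = 0, members = -id)
      } else {
        list(x = node_x[id], y = tree$height[id], members = node_members[[id]])
      }
    })
    h <- tree$height[node]
    members <- c(info[[1L]]$members, info[[2L]]$members)
    node_x[node] <- mean(c(info[[1L]]$x, info[[2L]]$x))
    node_members[[node]] <- members
    segs[[node]] <- data.frame(
      x0 = c(info[[1L]]$x, info[[2L]]$x, info[[1L]]$x),
      y0 = c(info[[1L]]$y, info[[2L]]$y, h),
      x1 = c(info[[1L]]$x, info[[2L]]$x, info[[2L]]$x),
      y1 = c(h, h, h),
      color = c(seg_color(node_cluster(info[[1L]]$members)),
                seg_color(node_cluster(info[[2L]]$members)),
                seg_color(node_cluster(members))),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, segs)
}
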