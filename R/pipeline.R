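#' Build an interactive cluster heatmap end to end
#'
#' The single entry point wiring every stage in a fixed order: transform the
#' matrix, then per axis compute distances, cluster agglomeratively,
#' optionally pick the number of clusters by mean silhouette, seriate the
#' dendrogram leaves by optimal leaf ordering, then map values to colors,
#' assemble the figure and write the requested files.
#'
#' Defaults mirror common practice for cluster heatmaps: Euclidean distance,
#' average (UPGMA) linkage, dendrograms on both axes, optimal-leaf-order
#' seriation, sequential viridis colors. Setting `col_dendrogram = FALSE`
#' keeps the columns in input order — the right choice when columns have an
#' intrinsic order such as years. `k_row = "auto"` searches k = 2..10 for
#' the cut with the highest mean silhouette and colors the branches by it.
#'
#' @param m Numeric matrix (or the path behaviours of [read_matrix()]
#'   applied beforehand). `NA` marks missing cells.
#' @param transform One of `"none"`, `"sqrt"`, `"scale"`, `"normalize"`,
#'   `"percentize"`, `"is_na10"` — applied before clustering (see
#'   [transforms]).
#' @param dist_method Distance metric, see [compute_distance()].
#' @param linkage Linkage function, see [agglomerate()].
#' @param row_dendrogram,col_dendrogram Logical: cluster (and draw a
#'   dendrogram for) this axis. A disabled axis keeps its input order.
#' @param k_row,k_col `NULL` (no branch coloring), `"auto"` (silhouette
#'   search over `k = 2..10`), or an integer number of clusters.
#' @param seriation `"OLO"` (default) or `"identity"`.
#' @param scale An `interheat_scale`, or `NULL` to pick the default for
#'   `data_kind` (see [pick_default_scale()]).
#' @param data_kind `"plain"` or `"correlation"`; a correlation matrix gets
#'   the divergent scale with limits \[-1, 1\].
#' @param annotations List of [annotation_track()]s aligned to the *input*
#'   matrix order; they are permuted together with the matrix.
#' @param files Character vector of output paths; extension selects the
#'   format (`.html` or `.png`).
#' @param cfg Layout options from [layout_config()].
#' @param width_px,height_px PNG dimensions.
#' @return The `interheat_figure` bundle, invisibly, with attributes
#'   `row_order`, `col_order`, `row_k`, `col_k`.
#' @export
#' @examples
#' m <- planted_clusters(3, 5, 4, separation = 10, noise_sd = 0.1, seed = 1)
#' fig <- interheat(m, k_row = "auto", files = character())
#' attr(fig, "row_k")  # 3 planted groups recovered
interheat <- function(m,
                      transform = c("none", "sqrt", "scale", "normalize",
                                    "percentize", "is_na10"),
                      dist_method = "euclidean",
                      linkage = "average",
                      row_dendrogram = TRUE,
                      col_dendrogram = TRUE,
                      k_row = NULL,
                      k_col = NULL,
                      seriation = c("OLO", "identity"),
                      scale = NULL,
                      data_kind = c("plain", "correlation"),
                      annotations = list(),
                      files = character(),
                      cfg = layout_config(),
                      width_px = 900, height_px = 700) {
  transform <- match.arg(transform)
  seriation <- match.arg(seriation)
  data_kind <- match.arg(data_kind)
  bad_ext <- files[!grepl("\\.(html|png)$", files)]
  if (length(bad_ext)) {
    stop("output paths must end in .html or .png: ",
         paste(bad_ext, collapse = ", "), call. = FALSE)
  }

  m <- .stage("input", validate_matrix(m))
  m <- .stage("transform", switch(transform,
    none = m,
    sqrt = sqrt_transform(m),
    scale = scale_columns(m),
    normalize = normalize_columns(m),
    percentize = percentize_columns(m),
    is_na10 = is_na10(m)
  ))

  row_axis <- .stage("row clustering",
                     .cluster_axis(m, row_dendrogram, dist_method, linkage,
                                   k_row, seriation))
  col_axis <- .stage("column clustering",
                     .cluster_axis(t(m), col_dendrogram, dist_method,
                                   linkage, k_col, seriation))

  m_perm <- .stage("reorder",
                   apply_order(m, row_axis$order, col_axis$order))
  annotations <- .stage("reorder", lapply(annotations, function(a) {
    ord <- if (a$axis == "row") row_axis$order else col_axis$order
    annotation_track(a$axis, a$name, a$categories[ord], a$level_order)
  }))

  if (is.null(scale)) scale <- pick_default_scale(data_kind)
  fig <- .stage("layout", build_figure(
    m_perm,
    row_tree = row_axis$tree, col_tree = col_axis$tree,
    row_clusters = row_axis$clusters, col_clusters = col_axis$clusters,
    annotations = annotations, scale = scale, cfg = cfg
  ))

  for (f in files) {
    if (grepl("\\.html$", f)) {
      .stage("html export", to_html(fig, f))
    } else {
      .stage("png export", to_png(fig, f, width_px, height_px))
    }
  }

  attr(fig, "row_order") <- row_axis$order
  attr(fig, "col_order") <- col_axis$order
  attr(fig, "row_k") <- if (!is.null(row_axis$clusters)) row_axis$clusters$k
  attr(fig, "col_k") <- if (!is.null(col_axis$clusters)) col_axis$clusters$k
  invisible(fig)
}

# Distance -> tree -> optional cluster cut -> seriation, for one axis.
# Returns order (permutation), tree (seriated hclust or NULL), clusters.
.cluster_axis <- function(m, enabled, dist_method, linkage, k, seriation) {
  n <- nrow(m)
  if (!enabled) {
    return(list(order = seq_len(n), tree = NULL, clusters = NULL))
  }
  d <- compute_distance(m, dist_method)
  tree <- agglomerate(d, linkage)
  clusters <- if (is.null(k)) {
    NULL
  } else if (identical(k, "auto")) {
    find_k(d, tree)
  } else {
    cut_tree(tree, as.integer(k), d = d)
  }
  sr <- olo_reorder(tree, d, method = seriation)
  if (!is.null(clusters)) {
    # renumber clusters by first appearance along the final leaf order
    first_seen <- unique(clusters$labels_by_leaf[sr$order])
    relabeled <- match(clusters$labels_by_leaf, first_seen)
    names(relabeled) <- names(clusters$labels_by_leaf)
    clusters$labels_by_leaf <- relabeled
  }
  list(order = sr$order, tree = sr$tree, clusters = clusters)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("in stage '", name, "': ", conditionMessage(e), call. = FALSE)
  })
}
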