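#' Pairwise distances between matrix rows
#'
#' Computes the distance matrix that drives row (or, on `t(m)`, column)
#' clustering. Missing cells are handled pairwise-complete: for the
#' `euclidean` and `manhattan` metrics the partial sum is rescaled by
#' `n_cols / n_jointly_observed` (the behaviour of [stats::dist()]), so
#' distances stay comparable across pairs with different missingness.
#' `pearson` is the correlation dissimilarity `1 - r` with pairwise-complete
#' observations.
#'
#' @param m Numeric matrix; rows are the objects to be compared.
#' @param metric One of `"euclidean"`, `"manhattan"`, `"maximum"`,
#'   `"pearson"`.
#' @return A [stats::dist] object with a `metric` attribute and the row
#'   labels of `m` as its `Labels`.
#' @export
#' @examples
#' m <- rbind(a = c(0, 0), b = c(3, 4))
#' compute_distance(m)  # 5: the 3-4-5 triangle
compute_distance <- function(m, metric = c("euclidean", "manhattan",
                                           "maximum", "pearson")) {
  metric <- match.arg(metric)
  m <- validate_matrix(m)
  if (nrow(m) < 2L) {
    stop("need at least two rows to compute distances", call. = FALSE)
  }
  d <- if (metric == "pearson") {
    r <- suppressWarnings(stats::cor(t(m), use = "pairwise.complete.obs"))
    stats::as.dist(1 - r)
  } else {
    stats::dist(m, method = metric)
  }
  bad <- which(!is.finite(as.vector(d)))
  if (length(bad) > 0L) {
    pair <- .dist_pair(bad[1L], attr(d, "Size"))
    stop("distance between rows '", rownames(m)[pair[1L]], "' and '",
         rownames(m)[pair[2L]],
         "' is undefined (no jointly observed columns, or zero variance ",
         "under the pearson metric)", call. = FALSE)
  }
  attr(d, "metric") <- metric
  d
}

# Row/column indices of element k of a dist vector of Size n.
.dist_pair <- function(k, n) {
  i <- 1L
  off <- 0L
  while (k > off + (n - i)) {
    off <- off + (n - i)
    i <- i + 1L
  }
  c(i, i + (k - off))
}

#' Agglomerative hierarchical clustering
#'
#' Thin, validated wrapper around [stats::hclust()]: builds the binary merge
#' tree (dendrogram) from a distance matrix under the chosen linkage.
#' `"ward"` means the Ward-D2 variant (squared-distance update), the
#' conventional reading in modern software. Merge heights are non-decreasing
#' for all four supported linkages.
#'
#' @param d A [stats::dist] object (see [compute_distance()]).
#' @param linkage One of `"single"`, `"complete"`, `"average"` (UPGMA),
#'   `"ward"`.
#' @return An [stats::hclust] tree.
#' @export
agglomerate <- function(d, linkage = c("average", "single", "complete",
                                       "ward")) {
  linkage <- match.arg(linkage)
  if (!inherits(d, "dist")) stop("d must be a dist object", call. = FALSE)
  if (attr(d, "Size") < 2L) stop("need at least two objects", call. = FALSE)
  method <- if (linkage == "ward") "ward.D2" else linkage
  stats::hclust(d, method = method)
}

#' Cut a dendrogram into k clusters
#'
#' Removes the `k - 1` highest merges of the tree. Cluster ids are renumbered
#' by first appearance along the tree's leaf order, so cluster 1 is always
#' the leftmost branch in a drawn dendrogram — the numbering that branch
#' coloring uses.
#'
#' @param tree An [stats::hclust] tree.
#' @param k Number of clusters, `1 <= k <= n`.
#' @param d Optional [stats::dist] object; when supplied and `k >= 2`, the
#'   assignment's `mean_silhouette` field is filled in.
#' @return An `interheat_clusters` list: `k`, `labels_by_leaf` (named integer
#'   vector in the tree's label order) and `mean_silhouette` (`NA` unless `d`
#'   was given).
#' @export
cut_tree <- function(tree, k, d = NULL) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (k < 1L || k > n) {
    stop("k must be between 1 and the number of leaves (", n, ")",
         call. = FALSE)
  }
  raw <- stats::cutree(tree, k = k)
  # renumber by first appearance along the displayed leaf order
  first_seen <- unique(raw[tree$order])
  labels_by_leaf <- match(raw, first_seen)
  names(labels_by_leaf) <- names(raw)
  sil <- if (!is.null(d) && k >= 2L) mean_silhouette(d, labels_by_leaf)
         else NA_real_
  structure(list(k = as.integer(k), labels_by_leaf = labels_by_leaf,
                 mean_silhouette = sil),
            class = "interheat_clusters")
}

#' Mean silhouette width of a partition
#'
#' For point `i` with within-cluster mean distance `a(i)` (self excluded) and
#' nearest-other-cluster mean distance `b(i)`, the silhouette is
#' `s(i) = (b(i) - a(i)) / max(a(i), b(i))`; points in singleton clusters
#' contribute `s(i) = 0`. Returns the average over all points — the score
#' that [find_k()] maximizes.
#'
#' @param d A [stats::dist] object.
#' @param clusters An `interheat_clusters` object from [cut_tree()], or an
#'   integer vector of cluster ids.
#' @return A single number in `[-1, 1]`.
#' @export
mean_silhouette <- function(d, clusters) {
  if (inherits(clusters, "interheat_clusters")) {
    clusters <- clusters$labels_by_leaf
  }
  cl <- as.integer(clusters)
  if (length(unique(cl)) < 2L) {
    stop("silhouette is undefined for fewer than 2 clusters", call. = FALSE)
  }
  D <- as.matrix(d)
  n <- nrow(D)
  if (length(cl) != n) {
    stop("cluster vector length does not match distance matrix", call. = FALSE)
  }
  sizes <- tabulate(match(cl, unique(cl)))
  names(sizes) <- unique(cl)
  # mean distance from each point to each cluster (self included for now)
  sums <- rowsum(D, group = cl)            # clusters x n, summed over members
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- as.character(cl[i])
    n_own <- sizes[[own]]
    if (n_own == 1L) { s[i] <- 0; next }
    a_i <- sums[own, i] / (n_own - 1L)
    others <- setdiff(rownames(sums), own)
    b_i <- min(sums[others, i] / sizes[others])
    s[i] <- if (a_i == 0 && b_i == 0) 0 else (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

#' Automatic selection of the number of clusters
#'
#' Evaluates cuts of an existing dendrogram for every `k` in
#' `k_min..k_max` (default 2..10, clipped to `n - 1`) and returns the cut
#' with the highest mean silhouette width. Only cuts of the supplied tree are
#' considered — the search colors the branches of one clustering, it does not
#' re-cluster per `k`. Ties go to the smallest `k`.
#'
#' @param d A [stats::dist] object.
#' @param tree An [stats::hclust] tree built from `d`.
#' @param k_min,k_max Search range for the number of clusters.
#' @return An `interheat_clusters` object with its `mean_silhouette` filled
#'   in, plus a `silhouette_by_k` attribute giving the whole score curve.
#' @export
find_k <- function(d, tree, k_min = 2L, k_max = 10L) {
  stopifnot(inherits(tree, "hclust"))
  n <- length(tree$order)
  if (n < 3L) {
    stop("need at least 3 leaves to search for a cluster count", call. = FALSE)
  }
  k_max <- min(k_max, n - 1L)
  if (k_min < 2L || k_min > k_max) {
    stop("invalid k range [", k_min, ", ", k_max, "]", call. = FALSE)
  }
  ks <- seq.int(k_min, k_max)
  cuts <- lapply(ks, function(k) cut_tree(tree, k, d = d))
  scores <- vapply(cuts, function(a) a$mean_silhouette, numeric(1))
  best <- cuts[[which.max(scores)]]   # which.max takes the first (smallest k)
  attr(best, "silhouette_by_k") <- stats::setNames(scores, ks)
  best
}
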