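#' Optimal-leaf-order seriation of a dendrogram
#'
#' A dendrogram with `n` leaves admits `2^(n-1)` leaf orders, one per
#' configuration of branch flips. Optimal leaf ordering picks the
#' configuration minimizing the sum of distances between adjacent leaves —
#' the Hamiltonian path length restricted by the tree structure — so that
#' similar rows end up next to each other without breaking the clustering.
#'
#' The search is exact: a dynamic program over states (subtree, leftmost
#' leaf, rightmost leaf). For an internal node with children `L` and `R`,
#' `cost(u, v) = min over (w in L, z in R) of cost_L(u, w) + d(w, z) +
#' cost_R(z, v)`, i.e. two min-plus matrix products per node; `O(n^3)` total.
#' Ties are broken deterministically by the smallest leaf index at every
#' choice point (root ends first, then junction leaves, top-down), so equal
#' inputs always yield the same order.
#'
#' @param tree An [stats::hclust] tree.
#' @param d The [stats::dist] object the tree was built from (or any
#'   distance on the same leaf set; labels must match).
#' @param method `"OLO"` (the optimization), `"identity"` (keep the tree's
#'   current leaf order) or `"reverse"`.
#' @return An `interheat_seriation` list: `order` (integer permutation of
#'   leaf indices), `cost` (adjacent-pair distance sum), `method`, and
#'   `tree` — a copy of the input tree with its `order` replaced, for
#'   drawing.
#' @export
#' @examples
#' m <- matrix(c(0, 1, 5, 2.5), ncol = 1,
#'             dimnames = list(letters[1:4], "x"))
#' d <- compute_distance(m)
#' sr <- olo_reorder(agglomerate(d, "average"), d)
#' sr$order; sr$cost
olo_reorder <- function(tree, d, method = c("OLO", "identity", "reverse")) {
  method <- match.arg(method)
  stopifnot(inherits(tree, "hclust"), inherits(d, "dist"))
  n <- length(tree$order)
  if (attr(d, "Size") != n ||
      (!is.null(tree$labels) && !is.null(attr(d, "Labels")) &&
       !identical(tree$labels, attr(d, "Labels")))) {
    stop("tree and distance matrix do not share the same leaf set",
         call. = FALSE)
  }
  D <- as.matrix(d)
  ord <- switch(method,
    identity = tree$order,
    reverse  = rev(tree$order),
    OLO      = .olo(tree, D)
  )
  out_tree <- tree
  out_tree$order <- ord
  structure(list(order = ord, cost = path_cost(ord, D), method = method,
                 tree = out_tree),
            class = "interheat_seriation")
}

#' Sum of distances between adjacent elements of an order
#'
#' @param order Integer permutation of `1..n`.
#' @param d Distance matrix (`n x n` matrix or [stats::dist]).
#' @return The Hamiltonian path length of the order.
#' @export
path_cost <- function(order, d) {
  D <- as.matrix(d)
  if (length(order) < 2L) return(0)
  sum(D[cbind(order[-length(order)], order[-1L])])
}

# Exact OLO dynamic program. Returns the optimal leaf-index order.
# For every internal node the cost matrix over (leftmost, rightmost) leaf
# pairs is built by two min-plus products; the argmin junction leaves are
# stored alongside, so the traceback replays the exact choices of the DP
# (no floating-point re-derivation). All leaf index vectors are kept sorted
# ascending, which makes every tie resolve to the smallest leaf index.
.olo <- function(tree, D) {
  n <- nrow(D)
  if (n == 1L) return(1L)
  merge <- tree$merge

  info <- vector("list", n - 1L)
  node_leaves <- function(id) if (id < 0L) -id else info[[id]]$leaves
  node_M <- function(id) {
    if (id < 0L) matrix(0, 1L, 1L, dimnames = list(-id, -id)) else
      info[[id]]$M
  }

  for (node in seq_len(n - 1L)) {
    a <- merge[node, 1L]; b <- merge[node, 2L]
    la <- sort(node_leaves(a)); lb <- sort(node_leaves(b))
    ca <- as.character(la); cb <- as.character(lb)
    Ma <- node_M(a)[ca, ca, drop = FALSE]
    Mb <- node_M(b)[cb, cb, drop = FALSE]
    # ends (u in la, v in lb): Ma (x) D[la, lb] (x) Mb with argmin tracking
    p1 <- .minplus_arg(Ma, D[la, lb, drop = FALSE], la)   # best w per (u, z)
    p2 <- .minplus_arg(p1$C, Mb, lb)                      # best z per (u, v)
    all_lv <- sort(c(la, lb))
    cl <- as.character(all_lv)
    full <- matrix(Inf, length(all_lv), length(all_lv),
                   dimnames = list(cl, cl))
    full[ca, cb] <- p2$C
    full[cb, ca] <- t(p2$C)   # path reversal symmetry
    info[[node]] <- list(leaves = all_lv, M = full, a = a, b = b,
                         la = la, lb = lb,
                         argW = `dimnames<-`(p1$K, list(ca, cb)),
                         argZ = `dimnames<-`(p2$K, list(ca, cb)))
  }

  root <- n - 1L
  Mr <- info[[root]]$M
  # smallest-index tie-break on the path ends: scan u, then v, ascending
  best <- min(Mr)
  idx <- info[[root]]$leaves
  found <- FALSE
  for (u in idx) {
    for (v in idx) {
      if (u != v && Mr[as.character(u), as.character(v)] == best) {
        found <- TRUE
        break
      }
    }
    if (found) break
  }

  trace <- function(id, u, v) {
    if (id < 0L) return(-id)
    nd <- info[[id]]
    if (u %in% nd$la) {
      z <- nd$argZ[as.character(u), as.character(v)]
      w <- nd$argW[as.character(u), as.character(z)]
      c(trace(nd$a, u, w), trace(nd$b, z, v))
    } else {
      # stored orientation is la -> lb; the (v, u) entry gives the reverse
      z <- nd$argZ[as.character(v), as.character(u)]
      w <- nd$argW[as.character(v), as.character(z)]
      c(trace(nd$b, u, z), trace(nd$a, w, v))
    }
  }
  trace(root, u, v)
}

# Min-plus matrix product with argmin: C[i, j] = min_k A[i, k] + B[k, j],
# K[i, j] = the leaf id ks[k] attaining it (first, i.e. smallest, on ties).
.minplus_arg <- function(A, B, ks) {
  C <- matrix(Inf, nrow(A), ncol(B))
  K <- matrix(NA_integer_, nrow(A), ncol(B))
  for (k in seq_along(ks)) {
    cand <- outer(A[, k], B[k, ], `+`)
    upd <- cand < C
    C[upd] <- cand[upd]
    K[upd] <- ks[k]
  }
  list(C = C, K = K)
}

#' Permute a matrix's rows and columns
#'
#' Applies leaf orders from seriation to the data matrix so that heatmap
#' rows/columns line up with dendrogram leaves. Labels move with their
#' rows/columns; the multiset of values is unchanged.
#'
#' @param m Numeric matrix.
#' @param row_order,col_order Integer permutations of the respective axis
#'   (or `NULL` to leave an axis untouched).
#' @return The permuted matrix.
#' @export
apply_order <- function(m, row_order = NULL, col_order = NULL) {
  m <- validate_matrix(m)
  if (!is.null(row_order)) {
    .check_permutation(row_order, nrow(m), "row")
    m <- m[row_order, , drop = FALSE]
  }
  if (!is.null(col_order)) {
    .check_permutation(col_order, ncol(m), "column")
    m <- m[, col_order, drop = FALSE]
  }
  m
}

.check_permutation <- function(p, n, what) {
  if (length(p) != n || !setequal(p, seq_len(n))) {
    stop("invalid ", what, " permutation: expected a rearrangement of 1..", n,
         call. = FALSE)
  }
}
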