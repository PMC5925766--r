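line_matrix <- function(v) {
  matrix(v, ncol = 1, dimnames = list(paste0("p", seq_along(v)), "x"))
}

test_that("compute_distance matches hand-computed values", {
  m <- rbind(a = c(0, 0), b = c(3, 4))
  colnames(m) <- c("x", "y")
  expect_equal(as.numeric(compute_distance(m)), 5)          # 3-4-5 triangle
  expect_equal(as.numeric(compute_distance(m, "manhattan")), 7)
  expect_equal(as.numeric(compute_distance(m, "maximum")), 4)

  same <- rbind(a = c(1, 2), b = c(1, 2))
  expect_equal(as.numeric(compute_distance(same)), 0)

  corr <- rbind(a = c(1, 2, 3), b = c(2, 4, 6))
  expect_equal(as.numeric(compute_distance(corr, "pearson")), 0,
               tolerance = 1e-12)                           # r = 1
})

test_that("pairwise-complete distances rescale by observed fraction", {
  m <- rbind(a = c(0, 0, 0, 0), b = c(1, 1, 1, NA))
  colnames(m) <- paste0("c", 1:4)
  # 3 of 4 columns observed: dist rescales squared sum by 4/3
  expect_equal(as.numeric(compute_distance(m)), sqrt(3 * 4 / 3))
  expect_equal(as.numeric(compute_distance(m, "manhattan")), 3 * 4 / 3)

  disjoint <- rbind(a = c(1, NA), b = c(NA, 1))
  colnames(disjoint) <- c("c1", "c2")
  expect_error(compute_distance(disjoint), "'a' and 'b'")
})

test_that("average linkage on the {0,1,5} line gives heights 1 and 4.5", {
  d <- compute_distance(line_matrix(c(0, 1, 5)))
  tree <- agglomerate(d, "average")
  expect_equal(tree$height, c(1, 4.5))   # UPGMA: (5 + 4) / 2
  # first merge joins points 0 and 1
  expect_setequal(-tree$merge[1, ], c(1, 2))
})

test_that("n = 2 yields a single merge at the pairwise distance", {
  d <- compute_distance(line_matrix(c(2, 7)))
  tree <- agglomerate(d, "single")
  expect_equal(tree$height, 5)
})

test_that("merge heights are non-decreasing for all four linkages", {
  for (linkage in c("single", "complete", "average", "ward")) {
    for (seed in 1:5) {
      m <- random_matrix(10, 4, seed)
      tree <- agglomerate(compute_distance(m), linkage)
      expect_true(all(diff(tree$height) >= -1e-12), label = linkage)
    }
  }
})

test_that("single-linkage merge heights equal sorted MST edge weights", {
  skip_if_not_installed("vegan")
  for (seed in 1:10) {
    n <- sample(4:12, 1)
    m <- random_matrix(n, 3, seed)
    d <- compute_distance(m)
    tree <- agglomerate(d, "single")
    mst <- vegan::spantree(d)
    expect_equal(sort(tree$height), sort(mst$dist), tolerance = 1e-12)
  }
})

test_that("cut_tree partitions the leaves and numbers by leaf order", {
  d <- compute_distance(line_matrix(c(0, 1, 5)))
  tree <- agglomerate(d, "average")
  a2 <- cut_tree(tree, 2)
  grp <- split(names(a2$labels_by_leaf), a2$labels_by_leaf)
  expect_setequal(grp[[which(lengths(grp) == 2)]], c("p1", "p2"))
  expect_setequal(grp[[which(lengths(grp) == 1)]], "p3")
  # id 1 is the leftmost cluster in display order
  expect_equal(unname(a2$labels_by_leaf[tree$order[1]]), 1L)

  n <- 8
  tree8 <- agglomerate(compute_distance(random_matrix(n, 3, 1)), "complete")
  expect_equal(sort(unique(cut_tree(tree8, n)$labels_by_leaf)), 1:n)
  expect_equal(unique(cut_tree(tree8, 1)$labels_by_leaf), 1L)
  for (k in 2:(n - 1)) {
    a <- cut_tree(tree8, k)
    expect_length(a$labels_by_leaf, n)
    expect_equal(length(unique(a$labels_by_leaf)), k)
  }
  expect_error(cut_tree(tree8, 0), "between 1 and")
  expect_error(cut_tree(tree8, n + 1), "between 1 and")
})

test_that("mean_silhouette matches direct computation on the 0,1,10,11 line", {
  m <- line_matrix(c(0, 1, 10, 11))
  d <- compute_distance(m)
  cl <- c(1L, 1L, 2L, 2L)
  # outer points: (10.5 - 1)/10.5; inner points: (9.5 - 1)/9.5
  expected <- (9.5 / 10.5 + 8.5 / 9.5) / 2
  expect_equal(mean_silhouette(d, cl), expected, tolerance = 1e-12)
  expect_equal(brute_silhouette(as.matrix(d), cl), expected,
               tolerance = 1e-12)
})

test_that("coincident clusters score 1; singletons contribute 0", {
  m <- line_matrix(c(0, 0, 9, 9))
  d <- compute_distance(m)
  expect_equal(mean_silhouette(d, c(1L, 1L, 2L, 2L)), 1)

  m3 <- line_matrix(c(0, 0.4, 9))
  d3 <- compute_distance(m3)
  s <- mean_silhouette(d3, c(1L, 1L, 2L))
  direct <- brute_silhouette(as.matrix(d3), c(1L, 1L, 2L))
  expect_equal(s, direct, tolerance = 1e-12)

  expect_error(mean_silhouette(d, c(1L, 1L, 1L, 1L)), "fewer than 2")
})

test_that("mean_silhouette agrees with brute force and cluster::silhouette", {
  has_cluster <- requireNamespace("cluster", quietly = TRUE)
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:30, 1)
    k <- sample(2:4, 1)
    m <- random_matrix(n, 3, seed)
    d <- compute_distance(m)
    cl <- sample(rep_len(seq_len(k), n))
    expect_equal(mean_silhouette(d, cl), brute_silhouette(as.matrix(d), cl),
                 tolerance = 1e-9)
    if (has_cluster && all(tabulate(cl) > 0)) {
      ref <- mean(cluster::silhouette(cl, d)[, "sil_width"])
      expect_equal(mean_silhouette(d, cl), ref, tolerance = 1e-9)
    }
  }
})

test_that("find_k returns the silhouette argmax over cuts of the tree", {
  m <- planted_clusters(3, 5, 4, separation = 10, noise_sd = 0.1, seed = 1)
  d <- compute_distance(m)
  tree <- agglomerate(d, "average")
  best <- find_k(d, tree)
  # independent argmax over all k
  scores <- sapply(2:10, function(k) {
    brute_silhouette(as.matrix(d), stats::cutree(tree, k))
  })
  expect_equal(best$k, (2:10)[which.max(scores)])
  expect_equal(best$k, 3L)
  expect_equal(best$mean_silhouette, max(scores), tolerance = 1e-9)
})

test_that("exact score ties resolve to the smallest k", {
  # regular simplex: all pairwise distances equal, every cut scores 0
  m <- diag(4) * 3
  dimnames(m) <- list(paste0("r", 1:4), paste0("c", 1:4))
  d <- compute_distance(m)
  tree <- agglomerate(d, "average")
  best <- find_k(d, tree)
  expect_equal(best$k, 2L)
  expect_true(all(abs(attr(best, "silhouette_by_k")) < 1e-12))
})

test_that("find_k rejects degenerate inputs and clips the range", {
  m2 <- random_matrix(2, 3, 1)
  d2 <- compute_distance(m2)
  expect_error(find_k(d2, agglomerate(d2, "average")), "at least 3")

  m5 <- random_matrix(5, 3, 1)
  d5 <- compute_distance(m5)
  best <- find_k(d5, agglomerate(d5, "average"))  # k_max clipped to 4
  expect_true(best$k <= 4)
  expect_length(attr(best, "silhouette_by_k"), 3L)
})
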