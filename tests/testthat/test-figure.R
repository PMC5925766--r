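tiny_figure <- function() {
  m <- matrix(c(1, 2, 3, 4), 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  build_figure(m)
}

clustered_figure <- function(seed = 1, k = NULL, annotations = list()) {
  m <- planted_clusters(3, 3, 4, separation = 8, noise_sd = 0.3, seed = seed)
  d <- compute_distance(m)
  tree <- agglomerate(d, "average")
  sr <- olo_reorder(tree, d)
  clusters <- if (!is.null(k)) cut_tree(sr$tree, k, d = d)
  mp <- apply_order(m, sr$order)
  ann <- lapply(annotations, function(a) {
    annotation_track(a$axis, a$name, a$categories[sr$order], a$level_order)
  })
  build_figure(mp, row_tree = sr$tree, row_clusters = clusters,
               annotations = ann)
}

test_that("a minimal 2x2 bundle has one tooltip per cell", {
  fig <- tiny_figure()
  expect_equal(length(fig$tooltips), 4L)
  expect_true(all(grepl("row: r[12]<br>column: c[12]<br>value: [1-4]",
                        fig$tooltips)))
  expect_null(fig$row_tree)
  expect_null(fig$col_tree)
})

test_that("heatmap rows align with the row dendrogram leaf order", {
  fig <- clustered_figure()
  leaf_labels <- fig$row_tree$labels[fig$row_tree$order]
  expect_identical(rownames(fig$values), leaf_labels)
  expect_identical(rownames(fig$values)[1], leaf_labels[1])
})

test_that("a misaligned matrix is rejected", {
  m <- random_matrix(5, 3, seed = 1)
  d <- compute_distance(m)
  tree <- agglomerate(d, "average")
  # matrix left unpermuted: only aligned if the tree order is the identity
  if (!identical(tree$order, 1:5)) {
    expect_error(build_figure(m, row_tree = tree), "leaf order")
  }
  expect_silent(build_figure(apply_order(m, tree$order), row_tree = tree))
})

test_that("k clusters produce exactly k branch colors below their roots", {
  fig <- clustered_figure(k = 3)
  seg <- fig$row_dendrogram
  non_neutral <- setdiff(unique(seg$color), "#5A5A5A")
  expect_length(non_neutral, 3L)
  expect_setequal(non_neutral, cluster_colors(3))
})

test_that("uncut dendrograms draw entirely in the neutral color", {
  fig <- clustered_figure(k = NULL)
  expect_identical(unique(fig$row_dendrogram$color), "#5A5A5A")
})

test_that("dendrogram segment geometry is consistent with the tree", {
  fig <- clustered_figure()
  seg <- fig$row_dendrogram
  n <- nrow(fig$values)
  expect_equal(nrow(seg), 3 * (n - 1))
  expect_true(all(seg$y1 >= 0))
  expect_equal(max(seg$y1), max(fig$row_tree$height))
  # leaf-adjacent verticals start at x = position - 0.5 for each leaf
  leaf_x <- sort(seg$x0[seg$y0 == 0])
  expect_equal(leaf_x, seq_len(n) - 0.5)
})

test_that("missing cells use na_color and tooltip value NA", {
  m <- matrix(c(1, NA, 3, 4), 2,
              dimnames = list(c("r1", "r2"), c("c1", "c2")))
  fig <- build_figure(m)
  expect_identical(fig$cell_colors[2, 1], fig$scale$na_color)
  expect_match(fig$tooltips[2, 1], "value: NA", fixed = TRUE)
})

test_that("emitted HTML is self-contained and carries every tooltip", {
  fig <- clustered_figure(k = 3)
  f <- tempfile(fileext = ".html")
  to_html(fig, f)
  txt <- paste(readLines(f, warn = FALSE), collapse = "\n")
  expect_length(external_refs(f), 0L)
  for (lab in c(rownames(fig$values), colnames(fig$values))) {
    expect_match(txt, lab, fixed = TRUE)
  }
  tips <- gsub("<br>", "&lt;br&gt;", as.vector(fig$tooltips), fixed = TRUE)
  for (tip in tips) expect_match(txt, tip, fixed = TRUE)
})

test_that("to_html is byte-deterministic", {
  fig <- clustered_figure(k = 2)
  f1 <- tempfile(fileext = ".html")
  f2 <- tempfile(fileext = ".html")
  to_html(fig, f1)
  to_html(fig, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("to_png writes a valid PNG of the requested dimensions", {
  for (fig in list(tiny_figure(), clustered_figure(k = 2))) {
    f <- tempfile(fileext = ".png")
    to_png(fig, f, width_px = 400, height_px = 300)
    sig <- readBin(f, "raw", 8)
    expect_identical(sig, as.raw(c(0x89, 0x50, 0x4e, 0x47,
                                   0x0d, 0x0a, 0x1a, 0x0a)))
    img <- png::readPNG(f)
    expect_identical(dim(img)[1:2], c(300L, 400L))
  }
  expect_error(to_png(tiny_figure(), tempfile(), width_px = 0), "positive")
})

test_that("annotation sidebars render with a legend", {
  ann <- list(list(axis = "row", name = "group",
                   categories = rep(c("a", "b", "c"), each = 3),
                   level_order = c("a", "b", "c")))
  fig <- clustered_figure(annotations = ann)
  expect_length(fig$annotations, 1L)
  f <- tempfile(fileext = ".html")
  to_html(fig, f)
  txt <- paste(readLines(f, warn = FALSE), collapse = "\n")
  expect_match(txt, "group:", fixed = TRUE)
})
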