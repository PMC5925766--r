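---
title: "Methods: how interheat builds a cluster heatmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: how interheat builds a cluster heatmap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interheat)
```

A cluster heatmap encodes a numeric matrix as colored tiles, reorders its
rows and columns by hierarchical clustering, and flanks the tiles with
dendrograms and categorical annotation bars. Every choice along the way —
how the data are scaled, which distance and linkage drive the clustering,
how many clusters to highlight, how the leaves are rotated, which colors
encode the values — changes the patterns a reader will see. This vignette
documents each of those choices as `interheat` makes them, and the
assumptions behind them.

## The pipeline and its fixed stage order

`interheat()` runs the stages in one fixed order: transform the matrix;
then, independently per axis, compute distances, agglomerate, optionally
select a cluster count, and seriate the dendrogram leaves; finally map
values to colors, assemble the figure and export it. The order matters —
distances are always computed on the *transformed* matrix, and cluster
counts are always selected on the same tree that is later drawn — so the
displayed dendrogram, its colored branches and the tile colors are mutually
consistent by construction. Running a transform yourself and passing
`transform = "none"` yields the identical figure.

## Transforms

Raw matrices rarely color well. Four per-column transforms (plus a
missingness indicator) are provided:

* **`sqrt_transform()`** — for right-tailed counts on a common unit (case
  rates, read counts). Pulls extreme cells toward the bulk so a few large
  values do not absorb the whole color range. Requires non-negative input
  and errors otherwise, naming the offending cell.
* **`scale_columns()`** — per-column z-score using the sample (n−1)
  standard deviation, the conventional definition in statistical software.
  Appropriate when columns are roughly normal.
* **`normalize_columns()`** — the affine min–max map `(x − min)/(max −
  min)` onto [0, 1], preserving each column's distribution shape.
* **`percentize_columns()`** — each value replaced by its own column's
  empirical CDF evaluated at that value: the fraction of observations at or
  below it. Output lies in (0, 1], ties map to identical outputs, and ranks
  are preserved; it is a rank transform with a direct probabilistic
  reading.

Missing values propagate (`NA` in, `NA` out) and are excluded from every
statistic: means, standard deviations, extrema, and the ECDF denominator.
Constant columns under `scale_columns()` / `normalize_columns()` map to all
zeros rather than erroring — a deliberate degenerate-input policy so that
pipelines over synthetic or sparse data do not abort on an uninformative
column. `is_na10()` returns the 0/1 missingness indicator for exploring
sparseness as a heatmap of its own.

## Distances and linkage

`compute_distance()` supports Euclidean (default), Manhattan, maximum and
Pearson-dissimilarity (1 − r) metrics. Missing cells are handled
pairwise-complete; for Euclidean and Manhattan the partial sum is rescaled
by `n_cols / n_jointly_observed`, so a pair with a few missing columns is
not spuriously close. A pair of rows with no jointly observed column has no
defined distance and raises an error naming the pair. Agglomeration is
delegated to `stats::hclust` — the standard, deterministic implementation —
under single, complete, average (UPGMA, the default) or Ward linkage;
"Ward" means the Ward-D2 variant (squared-distance update), its
conventional modern meaning. Merge heights are non-decreasing for all four,
so drawn dendrograms never invert.

## Choosing the number of clusters

With `k_row = "auto"` (or `k_col`), the package cuts the *already built*
tree at every k from 2 to 10 (clipped to n − 1) and keeps the cut with the
highest mean silhouette width, computed from the same distance matrix:
`s(i) = (b(i) − a(i)) / max(a(i), b(i))` with `a(i)` the mean within-cluster
distance (self excluded) and `b(i)` the smallest mean distance to another
cluster; singleton clusters contribute 0, the standard convention. Only
cuts of one tree are compared — the search colors the branches of a single
clustering rather than re-clustering per k, so the highlighted clusters are
always nested in the displayed dendrogram. Ties in the silhouette curve
resolve to the smallest k, the more parsimonious description. The curve
itself is returned as an attribute for inspection.

## Optimal leaf ordering

A dendrogram fixes the tree but not the leaf order: each of the n − 1
internal nodes can flip, giving 2^(n−1) orders. `olo_reorder()` solves for
the flip configuration minimizing the sum of distances between adjacent
leaves — the Hamiltonian path length restricted by the tree — exactly, by
dynamic programming over (subtree, leftmost leaf, rightmost leaf) states:
for an internal node, `cost(u, v) = min over junctions (w, z) of
cost_left(u, w) + d(w, z) + cost_right(z, v)`, two min-plus matrix products
per node, O(n³) overall. That bound is accepted deliberately: matrices that
render as legible heatmaps (hundreds of rows) are far below the scale where
O(n³) hurts, and exactness lets the test suite compare against exhaustive
flip enumeration.

Two numerical details matter. The argmin junctions are recorded during the
forward pass and replayed in the traceback; re-deriving them by comparing
recomputed floating-point sums is not reliable, because min-plus products
associate additions differently than a left-to-right re-summation. And all
ties — at the path ends and at every junction — resolve to the smallest
leaf index, top-down. This is a deterministic, locally lexicographic rule:
it guarantees reproducible output (the same input always yields the same
HTML bytes) without paying for a globally lexicographic argmin over all
cost-tied orders, which would require comparing whole candidate sequences
for no visible benefit.

Seriation is applied independently per axis, each with its own tree and
distances; an axis without a dendrogram (e.g. years in input order) is
left untouched.

## Color

The default scale is a sequential 11-stop viridis table: colorful,
monotone in luminance (so value order survives grayscale printing), and
robust to common color-vision deficiencies. Correlation matrices instead
get a divergent cool–warm scale with limits pinned to [−1, 1], putting the
neutral stop exactly at zero correlation; ColorBrewer's RdBu, BrBG and
RdYlBu are available as alternates. Palette stop tables are embedded as
fixed hex constants (sources documented in the code) so that rendered
output never depends on another package's version. Values are clamped to
the limits and interpolated piecewise-linearly in RGB between bracketing
stops — a simplicity trade-off versus interpolating in a perceptual space;
the luminance-monotonicity property that actually matters is enforced by
test at 11 sample points. Correlation mode is opt-in (`data_kind =
"correlation"`) rather than auto-detected from the value range, because a
plain matrix that happens to lie in [−1, 1] would otherwise silently get
the wrong scale. Missing cells render in mid-grey `#808080` with tooltip
value `NA`. Automatic limits are the finite data range; quantile clipping
of outliers is intentionally not done — use a transform instead.

## The figure and its exports

`build_figure()` assembles tiles, dendrograms, annotation sidebars, a
colorbar and per-cell tooltips into one bundle; both exporters consume the
same display list of drawing primitives, so the HTML and PNG depict the
identical layout. The matrix is drawn with row 1 at the top (reading
order); heatmap row i always equals row-dendrogram leaf i, enforced with an
error if the matrix was not permuted first. Branch segments at or below a
cluster's root take the cluster's categorical color; segments spanning
clusters are neutral grey.

The HTML file is fully self-contained: an inline SVG plus a small embedded
vanilla-JavaScript viewer providing hover tooltips on every cell
(template `row: {row}<br>column: {col}<br>value: {value}`, values at 6
significant digits), mouse-wheel zoom about the pointer, drag panning and
double-click reset. No script, font or style is fetched from anywhere, so
the file works offline and can be shipped as supplementary material.
Serialization is byte-deterministic — no timestamps, no generated
identifiers — which makes "same data, same figure" a testable contract.
PNG export draws the same primitives on the `grDevices` PNG device at the
requested pixel dimensions.

## Synthetic data generators

Because the package's guarantees are structural, the test fixtures are
generated, not shipped:

* `planted_clusters()` places row groups around centroids separated by
  `separation` per coordinate with Gaussian noise (`noise_sd`). The
  recovery studies use separation 10 against noise 0.1 — widely separated,
  tight clusters for which silhouette selection should essentially always
  find the planted k; recovery below 95% would indicate a defect, not hard
  data.
* `surveillance_counts()` emulates region-by-year infectious-disease
  incidence tables: Gamma-Poisson (negative-binomial) counts, baseline mean
  rate 180 per 100 000 with Gamma shape 1.2 (strongly right-tailed,
  overdispersed), log-normal region effects (sd 0.4), and a sharp drop to
  2% of baseline within three years of a vaccination-style intervention.
  These constants were chosen once to make the square-root transform and
  the keep-column-order mode demonstrably worthwhile, and are not tuned
  further.
* `sprinkle_missing()` masks an exact count of cells for missingness tests.

All generators take explicit seeds and restore the caller's RNG state.
What passing tests on these fixtures shows is that the machinery is
correct — exact OLO, correct silhouette arithmetic, faithful rendering.
What they do not show is performance on real data: planted spherical
Gaussian clusters are far cleaner than biological structure, and the
negative-binomial surveillance matrix has none of the spatial or temporal
autocorrelation of real incidence data. Cluster counts "recovered" here
say nothing about whether silhouette selection will flatter noisy omics
matrices.

## Problem sizes and verification

The test suite verifies OLO against exhaustive enumeration on 200 random
trees with 3–10 leaves (≤ 512 flip configurations each), single linkage
against minimum-spanning-tree edge weights on 100 instances (n ≤ 12, via
`vegan::spantree` as an independent oracle), silhouette arithmetic against
a brute-force double loop on 100 labeled instances (n ≤ 30, agreement to
1e−9, cross-checked against `cluster::silhouette`), and rendering contracts
across 25 randomized pipeline configurations. These sizes were picked to
make exhaustive oracles exact yet fast; the algorithms themselves have no
such limits. `scripts/acceptance.R` re-runs the same checks end to end and
writes the measured rates as JSON.

## Known limitations

* O(n³) OLO and O(n²) silhouette make matrices beyond a few thousand rows
  slow; the package targets figures, which stop being readable long before
  that.
* RGB-space color interpolation can traverse slightly desaturated
  mid-tones compared to Lab-space interpolation.
* The interactive viewer is intentionally minimal: no brushing, no linked
  views, no dendrogram-click subsetting.
* File formats are delimited text only; no Excel/HDF5/sparse inputs, and
  matrices must fit in memory.
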