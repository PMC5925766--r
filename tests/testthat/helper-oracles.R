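# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration and direct double loops.

# All leaf orders reachable from a dendrogram by branch flips (2^(n-1)).
flip_orders <- function(merge, node = nrow(merge)) {
  if (node < 0L) return(list(-node))
  left <- flip_orders(merge, merge[node, 1L])
  right <- flip_orders(merge, merge[node, 2L])
  out <- list()
  for (l in left) {
    for (r in right) {
      out[[length(out) + 1L]] <- c(l, r)
      out[[length(out) + 1L]] <- c(r, l)
    }
  }
  out
}

# Adjacent-pair distance sum of an order, written independently of path_cost.
brute_path_cost <- function(order, D) {
  s <- 0
  for (i in seq_len(length(order) - 1L)) s <- s + D[order[i], order[i + 1L]]
  s
}

# Direct-definition mean silhouette: double loop, no vectorization tricks.
brute_silhouette <- function(D, cl) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (length(own) == 0L) { s[i] <- 0; next }
    a_i <- mean(D[i, own])
    b_i <- Inf
    for (g in setdiff(unique(cl), cl[i])) {
      b_i <- min(b_i, mean(D[i, which(cl == g)]))
    }
    s[i] <- if (max(a_i, b_i) == 0) 0 else (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

# Random labeled matrix with unique dimnames.
random_matrix <- function(n, p, seed) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(paste0("r", seq_len(n)), paste0("c", seq_len(p))))
}

write_temp_csv <- function(lines) {
  f <- tempfile(fileext = ".csv")
  writeLines(lines, f)
  f
}

# External-resource audit of an emitted HTML file: no src/href/url()/import
# pointing at a URL. (Namespace identifiers like xmlns="..." are not
# resource references.)
external_refs <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  hits <- c(
    regmatches(txt, gregexpr("src\\s*=\\s*[\"'][^\"']*", txt))[[1L]],
    regmatches(txt, gregexpr("href\\s*=\\s*[\"'][^\"']*", txt))[[1L]],
    regmatches(txt, gregexpr("url\\(", txt))[[1L]],
    regmatches(txt, gregexpr("@import", txt))[[1L]],
    regmatches(txt, gregexpr("fetch\\(", txt))[[1L]]
  )
  hits[grepl("http|//|fetch|url\\(|@import", hits)]
}
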