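#' Matrix transforms for comparable color scales
#'
#' Raw data matrices often mix scales across columns, or carry right-tailed
#' count distributions where a handful of extreme cells would absorb the whole
#' color range. These transforms bring cells onto a comparable scale before
#' clustering and color mapping. All of them preserve shape, dimnames and
#' (except [is_na10()]) the missing-value mask; missing cells propagate as
#' `NA` and are excluded from the statistics (mean, sd, min, max, ECDF
#' denominator).
#'
#' * `sqrt_transform()` — square root of every cell, pulling extreme counts in
#'   toward the bulk. Requires non-negative values.
#' * `scale_columns()` — per-column z-score: subtract the mean, divide by the
#'   sample (n-1) standard deviation. Suited to roughly normal columns.
#' * `normalize_columns()` — per-column min-max map onto \[0, 1\], preserving
#'   each column's distribution shape.
#' * `percentize_columns()` — per-column empirical CDF evaluated at each
#'   value: the fraction of observations at or below it, in (0, 1\].
#' * `is_na10()` — 0/1 indicator of missingness, for exploring sparseness.
#'
#' Constant columns under `scale_columns()` / `normalize_columns()` map to all
#' zeros rather than erroring, so pipelines on degenerate data keep running.
#'
#' @param m Numeric matrix (row/column labels optional; see
#'   [read_matrix()]). `NA` marks missing cells.
#' @param margin `"column"` (default, matching the usual per-variable
#'   framing), `"row"`, or `"global"` — the slice over which statistics are
#'   taken.
#' @return A numeric matrix of the same shape and dimnames.
#' @name transforms
NULL

#' @rdname transforms
#' @export
sqrt_transform <- function(m) {
  m <- validate_matrix(m)
  neg <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0L) {
    stop("sqrt_transform requires non-negative values; first offender at row '",
         rownames(m)[neg[1, 1]], "', column '", colnames(m)[neg[1, 2]], "'",
         call. = FALSE)
  }
  sqrt(m)
}

#' @rdname transforms
#' @export
scale_columns <- function(m, margin = c("column", "row", "global")) {
  margin <- match.arg(margin)
  apply_margin(validate_matrix(m), margin, function(v) {
    n_obs <- sum(!is.na(v))
    if (n_obs < 2L) {
      stop("scale_columns needs >= 2 non-missing values per slice",
           call. = FALSE)
    }
    s <- stats::sd(v, na.rm = TRUE)
    if (s == 0) return(ifelse(is.na(v), NA_real_, 0))
    (v - mean(v, na.rm = TRUE)) / s
  })
}

#' @rdname transforms
#' @export
normalize_columns <- function(m, margin = c("column", "row", "global")) {
  margin <- match.arg(margin)
  apply_margin(validate_matrix(m), margin, function(v) {
    if (all(is.na(v))) {
      stop("normalize_columns needs >= 1 non-missing value per slice",
           call. = FALSE)
    }
    lo <- min(v, na.rm = TRUE)
    hi <- max(v, na.rm = TRUE)
    if (hi == lo) return(ifelse(is.na(v), NA_real_, 0))
    (v - lo) / (hi - lo)
  })
}

#' @rdname transforms
#' @export
percentize_columns <- function(m, margin = c("column", "row", "global")) {
  margin <- match.arg(margin)
  apply_margin(validate_matrix(m), margin, function(v) {
    obs <- v[!is.na(v)]
    if (length(obs) == 0L) {
      stop("percentize_columns needs >= 1 non-missing value per slice",
           call. = FALSE)
    }
    out <- rep(NA_real_, length(v))
    out[!is.na(v)] <- stats::ecdf(obs)(obs)
    out
  })
}

#' @rdname transforms
#' @export
is_na10 <- function(m) {
  m <- validate_matrix(m)
  out <- m
  out[] <- as.numeric(is.na(m))
  out
}

# Apply f slice-wise while keeping shape and dimnames intact.
apply_margin <- function(m, margin, f) {
  out <- m
  switch(margin,
    column = for (j in seq_len(ncol(m))) out[, j] <- f(m[, j]),
    row    = for (i in seq_len(nrow(m))) out[i, ] <- f(m[i, ]),
    global = out[] <- f(as.vector(m))
  )
  out
}
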