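#' Synthetic matrices with planted cluster structure
#'
#' Generates a matrix whose rows fall into `n_clusters` groups around
#' centroids separated by `separation` in every coordinate, with i.i.d.
#' Gaussian noise. Row labels encode the true group (`g<cluster>_r<row>`),
#' so recovery tests can compare a clustering against the ground truth.
#' Generation is fully determined by `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param n_clusters Number of planted groups.
#' @param rows_per_cluster Rows per group.
#' @param n_cols Number of columns.
#' @param separation Distance between consecutive centroids per coordinate.
#' @param noise_sd Standard deviation of the Gaussian noise.
#' @param seed Integer seed.
#' @return Numeric matrix with `n_clusters * rows_per_cluster` rows and a
#'   `true_clusters` attribute (integer vector of planted group ids).
#' @export
planted_clusters <- function(n_clusters, rows_per_cluster, n_cols,
                             separation = 10, noise_sd = 0.1, seed = 1L) {
  stopifnot(n_clusters >= 1, rows_per_cluster >= 1, n_cols >= 1,
            separation > 0, noise_sd >= 0)
  .with_seed(seed, {
    truth <- rep(seq_len(n_clusters), each = rows_per_cluster)
    centroids <- matrix(rep((truth - 1) * separation, n_cols),
                        ncol = n_cols)
    noise <- matrix(stats::rnorm(length(truth) * n_cols, sd = noise_sd),
                    ncol = n_cols)
    m <- centroids + noise
    rownames(m) <- paste0("g", truth, "_r", seq_along(truth))
    colnames(m) <- paste0("v", seq_len(n_cols))
    attr(m, "true_clusters") <- truth
    m
  })
}

#' Synthetic surveillance-style count matrix
#'
#' Emulates the structure of disease-surveillance incidence tables (regions
#' by years of case rates): non-negative, right-tailed overdispersed counts
#' generated from a Gamma-Poisson (negative-binomial) mixture, with a sharp
#' drop in the underlying rate from the intervention year onward. The
#' right-tailed distribution makes the square-root transform worthwhile, and
#' the intrinsic year order makes `col_dendrogram = FALSE` the natural mode.
#'
#' Constants: pre-intervention mean rate 180 cases per 100 000, Gamma shape
#' 1.2 (strong overdispersion), region effects log-normal(sd 0.4), rate
#' falling to 2% of baseline within 3 years of the intervention.
#'
#' @param n_regions Number of rows (regions).
#' @param n_years Number of columns (years).
#' @param intervention_year_index 1-based column index of the intervention;
#'   columns from this index on have the reduced rate.
#' @param seed Integer seed.
#' @return Numeric `n_regions x n_years` matrix of counts.
#' @export
surveillance_counts <- function(n_regions = 50, n_years = 40,
                                intervention_year_index = 25, seed = 1L) {
  stopifnot(n_regions >= 1, n_years >= 1,
            intervention_year_index >= 1,
            intervention_year_index <= n_years)
  base_rate <- 180
  shape <- 1.2
  .with_seed(seed, {
    region_effect <- exp(stats::rnorm(n_regions, sd = 0.4))
    yr <- seq_len(n_years)
    decay <- ifelse(yr < intervention_year_index, 1,
                    pmax(0.02, 0.02^((yr - intervention_year_index + 1) / 3)))
    mu <- outer(region_effect, base_rate * decay)
    lambda <- matrix(stats::rgamma(length(mu), shape = shape,
                                   rate = shape / pmax(mu, 1e-9)),
                     nrow = n_regions)
    m <- matrix(stats::rpois(length(lambda), lambda), nrow = n_regions)
    rownames(m) <- paste0("region", seq_len(n_regions))
    colnames(m) <- paste0("year", yr)
    m
  })
}

#' Mask a fixed fraction of cells as missing
#'
#' Replaces exactly `round(fraction * n_cells)` cells with `NA`, chosen
#' uniformly at random but deterministically per seed.
#'
#' @param m Numeric matrix.
#' @param fraction Fraction of cells to mask, in `[0, 1)`.
#' @param seed Integer seed.
#' @return The matrix with masked cells set to `NA`.
#' @export
sprinkle_missing <- function(m, fraction, seed = 1L) {
  m <- validate_matrix(m)
  stopifnot(fraction >= 0, fraction < 1)
  n_mask <- round(fraction * length(m))
  if (n_mask == 0L) return(m)
  .with_seed(seed, {
    idx <- sample.int(length(m), n_mask)
    m[idx] <- NA_real_
    m
  })
}

# Evaluate expr under a private RNG stream, restoring global state after.
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
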