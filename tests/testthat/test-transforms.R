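mk <- function(v, nc = 1) {
  matrix(v, ncol = nc,
         dimnames = list(paste0("r", seq_len(length(v) / nc)),
                         paste0("c", seq_len(nc))))
}

test_that("sqrt_transform takes exact roots and rejects negatives", {
  m <- matrix(c(0, 9, 4, 16), 2,
              dimnames = list(c("r1", "r2"), c("a", "b")))
  expect_identical(sqrt_transform(m),
                   matrix(c(0, 3, 2, 4), 2,
                          dimnames = dimnames(m)))
  z <- mk(c(0, 0, 0))
  expect_identical(sqrt_transform(z), z)
  m[2, 1] <- -1
  expect_error(sqrt_transform(m), "non-negative.*r2.*a")
})

test_that("scale_columns z-scores with sample sd and handles edge cases", {
  expect_equal(as.vector(scale_columns(mk(c(1, 2, 3)))), c(-1, 0, 1))
  expect_equal(as.vector(scale_columns(mk(c(5, 5, 5)))), c(0, 0, 0))
  expect_equal(as.vector(scale_columns(mk(c(2, 4)))),
               c(-1, 1) / sqrt(2))     # sd = sqrt(2), hand computation
  expect_error(scale_columns(mk(c(1, NA, NA))), ">= 2 non-missing")
})

test_that("normalize_columns maps onto [0,1] affinely", {
  expect_equal(as.vector(normalize_columns(mk(c(2, 4, 6)))), c(0, 0.5, 1))
  expect_equal(as.vector(normalize_columns(mk(c(-1, 1)))), c(0, 1))
  expect_equal(as.vector(normalize_columns(mk(c(3, 3, 3)))), c(0, 0, 0))
})

test_that("percentize_columns is the per-column ECDF at own values", {
  expect_equal(as.vector(percentize_columns(mk(c(10, 20, 30, 40)))),
               c(0.25, 0.5, 0.75, 1))
  expect_equal(as.vector(percentize_columns(mk(c(1, 1, 3)))),
               c(2 / 3, 2 / 3, 1))
  # NA is excluded from the denominator and propagates
  expect_equal(as.vector(percentize_columns(mk(c(1, NA, 2)))),
               c(0.5, NA, 1))
})

test_that("percentize agrees with a brute-force counting oracle", {
  for (seed in 1:10) {
    m <- random_matrix(12, 5, seed)
    m <- sprinkle_missing(m, 0.15, seed = seed)
    p <- percentize_columns(m)
    for (j in seq_len(ncol(m))) {
      obs <- m[!is.na(m[, j]), j]
      for (i in seq_len(nrow(m))) {
        if (is.na(m[i, j])) {
          expect_true(is.na(p[i, j]))
        } else {
          expect_equal(p[i, j], sum(obs <= m[i, j]) / length(obs))
        }
      }
    }
  }
})

test_that("is_na10 is the 0/1 missingness indicator", {
  m <- mk(c(1, NA, NA, 4), nc = 2)
  expect_identical(as.vector(is_na10(m)), c(0, 1, 1, 0))
  expect_false(anyNA(is_na10(m)))
  all_na <- mk(c(NA_real_, NA_real_))
  expect_identical(as.vector(is_na10(all_na)), c(1, 1))
})

test_that("transform properties hold on random matrices with missing cells", {
  for (seed in 1:8) {
    m <- random_matrix(15, 6, seed)
    if (seed %% 2 == 0) m <- sprinkle_missing(m, 0.1, seed = seed)

    sc <- scale_columns(m)
    expect_lt(max(abs(colMeans(sc, na.rm = TRUE))), 1e-12)
    expect_lt(max(abs(apply(sc, 2, sd, na.rm = TRUE) - 1)), 1e-12)

    nm <- normalize_columns(m)
    expect_equal(normalize_columns(nm), nm)          # idempotent
    expect_true(all(nm >= 0 & nm <= 1, na.rm = TRUE))

    p <- percentize_columns(m)
    expect_true(all(p > 0 & p <= 1, na.rm = TRUE))
    for (j in seq_len(ncol(m))) {                    # rank preserving
      ok <- !is.na(m[, j])
      expect_true(all(diff(p[ok, j][order(m[ok, j])]) >= 0))
    }

    # shape, labels and mask survive every transform
    for (f in list(scale_columns, normalize_columns, percentize_columns)) {
      out <- f(m)
      expect_identical(dimnames(out), dimnames(m))
      expect_identical(is.na(out), is.na(m))
    }
  }
})

test_that("row and global margins are available", {
  m <- random_matrix(4, 6, seed = 3)
  sr <- scale_columns(m, margin = "row")
  expect_lt(max(abs(rowMeans(sr))), 1e-12)
  ng <- normalize_columns(m, margin = "global")
  expect_equal(range(ng), c(0, 1))
})
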