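test_that("log transform maps intensities to log2 and zeros to missing", {
  x <- matrix(c(8, 1, 0, 4), 2, 2, dimnames = list(c("A", "B"), c("s1", "s2")))
  m <- log_transform(x)
  expect_equal(m$values["A", "s1"], 3)
  expect_equal(m$values["B", "s1"], 0)
  expect_true(is.na(m$values["A", "s2"]))
  expect_false(any(m$imputed))
  expect_error(log_transform(matrix(-1, 1, 1)), "negative")
})

test_that("missingness filter boundary is exact at max_missing", {
  vals <- matrix(rnorm(3 * 18), 3, 18,
                 dimnames = list(c("full", "six", "seven"), paste0("s", 1:18)))
  vals["six", 1:6] <- NA
  vals["seven", 1:7] <- NA
  m <- filter_missingness(intensity_matrix(vals), max_missing = 6)
  expect_equal(rownames(m$values), c("full", "six"))
  # complete matrix passes unchanged
  complete <- intensity_matrix(matrix(1:6, 2, 3))
  expect_identical(filter_missingness(complete)$values, complete$values)
})

test_that("kNN imputation is the identity on complete matrices and matches a
           hand-computed nearest neighbour", {
  complete <- im(matrix(rnorm(20), 4, 5))
  expect_identical(knn_impute(complete, k = 2)$values, complete$values)

  x <- rbind(P1 = c(1, 2, 3), P2 = c(1, 2, NA), P3 = c(10, 20, 30))
  colnames(x) <- paste0("s", 1:3)
  out <- knn_impute(intensity_matrix(x), k = 1)
  # P1 is at scaled distance 0 from P2 over co-observed samples; P3 is far
  expect_equal(out$values["P2", "s3"], 3)
  expect_true(out$imputed["P2", "s3"])
  expect_equal(sum(out$imputed), 1L)
})

test_that("kNN imputation never alters observed entries", {
  set.seed(5)
  for (rep in 1:5) {
    x <- matrix(rnorm(40 * 10, 20, 2), 40, 10)
    mask <- matrix(runif(length(x)) < 0.1, 40, 10)
    # keep at least one observed value per row
    mask[cbind(1:40, sample(10, 40, TRUE))] <- FALSE
    x[mask] <- NA
    out <- knn_impute(intensity_matrix(x), k = 3)
    expect_identical(out$values[!mask], x[!mask])
    expect_identical(unname(out$imputed), unname(mask))
    expect_false(anyNA(out$values))
  }
})

test_that("kNN beats per-protein-mean imputation on masked cells", {
  set.seed(17)
  n <- 500
  base <- rnorm(n, 25, 2)
  # condition structure: half the proteins carry a +2.5 effect in the last
  # six samples (activation-like); row means ignore it, neighbours share it
  effect <- outer(rep(c(0, 2.5), length.out = n),
                  rep(c(0, 1), c(12, 6)))
  x <- base + effect + matrix(rnorm(n * 18, 0, 0.3), n, 18)
  mask <- matrix(runif(length(x)) < 0.05, n, 18)
  mask[cbind(1:n, sample(18, n, TRUE))] <- FALSE
  xm <- x
  xm[mask] <- NA
  imputed <- knn_impute(intensity_matrix(xm), k = 10)$values
  rmse_knn <- sqrt(mean((imputed[mask] - x[mask])^2))
  rowm <- rowMeans(xm, na.rm = TRUE)
  rmse_mean <- sqrt(mean((rowm[row(x)[mask]] - x[mask])^2))
  expect_lt(rmse_knn, rmse_mean)
})

test_that("kNN falls back with a warning when neighbours are scarce", {
  x <- rbind(P1 = c(1, NA, NA), P2 = c(1.1, 2, NA), P3 = c(1.2, 2.1, 3))
  colnames(x) <- paste0("s", 1:3)
  expect_warning(out <- knn_impute(intensity_matrix(x), k = 5),
                 "fewer than k")
  expect_false(anyNA(out$values))
  expect_error(
    knn_impute(intensity_matrix(rbind(A = c(NA_real_, NA_real_),
                                      B = c(1, 2)))),
    "no observed values")
})

test_that("quantile normalization equalizes column distributions with the
           average-tie rule", {
  # hand example: columns (1,3) and (2,4) -> both (1.5, 3.5)
  x <- cbind(a = c(1, 3), b = c(2, 4))
  out <- quantile_normalize(x)
  expect_equal(unname(out), cbind(c(1.5, 3.5), c(1.5, 3.5)))
  # identical columns unchanged
  y <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(unname(quantile_normalize(y)), unname(y))
  # sorted columns identical afterwards, rank order preserved, idempotent
  set.seed(3)
  z <- matrix(rnorm(60, 20), 12, 5)
  qn <- quantile_normalize(z)
  sorted <- apply(qn, 2, sort)
  expect_equal(max(abs(sorted - sorted[, 1])), 0)
  for (j in 1:5) expect_equal(rank(qn[, j]), rank(z[, j]))
  expect_equal(quantile_normalize(qn), qn)
})

test_that("quantile normalization matches the reference implementation on ties", {
  set.seed(9)
  z <- matrix(sample(1:6, 48, replace = TRUE), 8, 6)  # many ties
  expect_equal(unname(quantile_normalize(z)),
               unname(limma::normalizeQuantiles(z, ties = TRUE)))
})

test_that("normalization refuses incomplete matrices; pipeline order enforced", {
  x <- matrix(c(1, NA, 3, 4), 2, 2)
  expect_error(quantile_normalize(x), "missing")
  expect_error(quantile_normalize(intensity_matrix(x)), "missing")
})
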