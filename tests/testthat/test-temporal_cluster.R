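make_blobs <- function(k, n_per = 20, sep = 10, sd = 0.3, seed = 21,
                       dims = 3) {
  set.seed(seed)
  centers <- matrix(sep * seq_len(k), k, dims)
  x <- do.call(rbind, lapply(seq_len(k), function(i) {
    matrix(rnorm(n_per * dims, centers[i, ], sd), n_per, dims, byrow = TRUE)
  }))
  rownames(x) <- paste0("P", seq_len(nrow(x)))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

test_that("k-means recovers well-separated planted blobs and centroids are
           member means", {
  blobs <- make_blobs(2)
  res <- kmeans_profiles(blobs$x, k = 2, seed = 3)
  # partition equals planted labels up to label permutation
  expect_equal(length(unique(paste(res$cluster, blobs$labels))), 2L)
  for (cl in 1:2) {
    expect_equal(unname(res$centroids[cl, ]),
                 unname(colMeans(blobs$x[res$cluster == cl, , drop = FALSE])),
                 tolerance = 1e-9)
  }
  # objective equals recomputed WCSS
  wcss <- sum(vapply(1:2, function(cl) {
    sub <- blobs$x[res$cluster == cl, , drop = FALSE]
    sum(sweep(sub, 2, colMeans(sub))^2)
  }, numeric(1)))
  expect_equal(res$objective, wcss, tolerance = 1e-9)
  expect_error(kmeans_profiles(blobs$x, k = 100), "exceeds")
})

test_that("identical seeds give identical assignments", {
  blobs <- make_blobs(3, sd = 2)
  a <- kmeans_profiles(blobs$x, 3, seed = 7)
  b <- kmeans_profiles(blobs$x, 3, seed = 7)
  expect_identical(a$cluster, b$cluster)
  expect_identical(a$centroids, b$centroids)
})

test_that("validity indices match brute-force oracles on small toys", {
  # Dunn on a 4-point 1-d example: within diameters 1, between min 9
  x4 <- matrix(c(0, 1, 10, 11), ncol = 1)
  cl4 <- c(1, 1, 2, 2)
  expect_equal(dunn_index(x4, cl4), 9)
  expect_equal(dunn_index(x4, cl4), dunn_oracle(x4, cl4))

  # connectivity on a 6-point toy with one boundary point, L = 2 neighbours
  x6 <- matrix(c(0, 1, 2, 10, 11, 12), ncol = 1)
  cl6 <- c(1, 1, 2, 2, 2, 2)
  expect_equal(connectivity_index(x6, cl6, n_neighbors = 2),
               connectivity_oracle(x6, cl6, L = 2))
  # a perfectly separated partition has zero connectivity
  expect_equal(connectivity_index(x6, c(1, 1, 1, 2, 2, 2)), 0)

  # silhouette against the hand-loop formula on an 8-point toy
  set.seed(31)
  x8 <- matrix(rnorm(16), 8, 2)
  cl8 <- rep(1:2, each = 4)
  expect_equal(silhouette_index(x8, cl8), silhouette_oracle(x8, cl8))
  expect_gte(silhouette_index(x8, cl8), -1)
  expect_lte(silhouette_index(x8, cl8), 1)
})

test_that("validity indices are invariant under label permutation", {
  blobs <- make_blobs(3, n_per = 8, sd = 1)
  cl <- kmeans_profiles(blobs$x, 3, seed = 5)$cluster
  perm <- c(2, 3, 1)[cl]
  expect_equal(silhouette_index(blobs$x, cl), silhouette_index(blobs$x, perm))
  expect_equal(dunn_index(blobs$x, cl), dunn_index(blobs$x, perm))
  expect_equal(connectivity_index(blobs$x, cl),
               connectivity_index(blobs$x, perm))
})

test_that("silhouette-based selection finds k = 3 on three planted blobs", {
  blobs <- make_blobs(3)
  sel <- select_k(blobs$x, k_range = 2:8, seed = 9)
  expect_equal(sel$k_star, 3L)
  expect_equal(sel$validity$k, 2:8)
  expect_true(all(sel$validity$silhouette >= -1 &
                    sel$validity$silhouette <= 1))
  expect_true(all(sel$validity$dunn > 0))
  expect_error(select_k(matrix(1, 5, 3)), "identical")
})

test_that("fold-change profile matrix aligns proteins with contrasts", {
  rows <- data.frame(
    protein_id = rep(c("A", "B"), 3),
    contrast = rep(c("c5", "c10", "c15"), each = 2),
    log2fc = c(1, 2, 3, 4, 5, 6),
    adj_p = 0.01, significant = TRUE, strong_change = TRUE,
    stringsAsFactors = FALSE)
  fc <- fc_profile_matrix(rows, proteins = c("B", "A"))
  expect_equal(dim(fc), c(2L, 3L))
  expect_equal(fc["A", "c10"], 3)
  expect_equal(fc["B", "c15"], 6)
})
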