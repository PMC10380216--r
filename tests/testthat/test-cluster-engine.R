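test_that("Pearson distance matches its definition and flags degenerate input", {
  set.seed(3)
  X <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, paste0("r", 1:4)))
  D <- pearson_distance(X)
  for (i in 1:4) for (j in 1:4)
    expect_equal(D[i, j], 1 - cor(X[, i], X[, j]), tolerance = 1e-12)
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)

  X2 <- cbind(a = 1:6, b = 1:6)
  expect_equal(pearson_distance(X2)["a", "b"], 0)
  X3 <- cbind(a = 1:6, b = 6:1)
  expect_equal(pearson_distance(X3)["a", "b"], 2)
  X4 <- cbind(a = 1:6, flat = rep(1, 6))
  expect_error(pearson_distance(X4), "flat")
})

test_that("PAM recovers separated blobs and matches the exhaustive 2-medoid oracle", {
  blobs <- make_blobs(n_per = 5, seed = 2)
  D <- pearson_distance(blobs$X)
  fit <- pam_cluster(D, 2)
  expect_equal(adjusted_rand_index(fit$labels, blobs$labels), 1)
  oracle <- oracle_best_2medoids(D)
  expect_equal(fit$cost, oracle$cost, tolerance = 1e-12)
  expect_setequal(fit$medoids, oracle$medoids)

  # k = n: every point its own medoid, zero cost
  fit_n <- pam_cluster(D, nrow(D))
  expect_equal(fit_n$cost, 0)
  expect_equal(sort(fit_n$medoids), seq_len(nrow(D)))
  expect_error(pam_cluster(D, nrow(D) + 1), "exceeds")
})

test_that("a single full-data replicate gives the 0/1 co-membership matrix", {
  blobs <- make_blobs(n_per = 4, seed = 5)
  res <- consensus_cluster(blobs$X, k_range = 2, reps = 1,
                           p_item = 1, p_feature = 1, seed = 1)
  M <- res$consensus[["2"]]
  lab <- pam_cluster(pearson_distance(scale_rows(blobs$X)), 2)$labels
  expect_equal(M, outer(lab, lab, function(a, b) (a == b) + 0),
               ignore_attr = TRUE)
})

test_that("consensus clustering recovers three planted clusters and the delta-area picks K = 3", {
  set.seed(9)
  n_per <- 6
  n_feat <- 40
  centers <- matrix(rnorm(n_feat * 3, sd = 4), n_feat, 3)
  X <- do.call(cbind, lapply(1:3, function(k)
    centers[, k] + matrix(rnorm(n_feat * n_per, 0, 0.3), n_feat)))
  colnames(X) <- paste0("item", seq_len(3 * n_per))
  truth <- rep(1:3, each = n_per)
  res <- consensus_cluster(X, k_range = 2:5, reps = 100, seed = 7)
  M3 <- res$consensus[["3"]]
  expect_true(all(M3 >= 0 & M3 <= 1))
  expect_equal(M3, t(M3))
  expect_equal(adjusted_rand_index(res$labels[["3"]], truth), 1)
  off_block <- M3[outer(truth, truth, `!=`)]
  expect_lt(mean(off_block), 0.1)
  expect_equal(select_k_delta_area(res)$k, 3)
})

test_that("structureless data yields the smallest K", {
  set.seed(13)
  X <- matrix(rnorm(40 * 15), 40, 15, dimnames = list(NULL, paste0("r", 1:15)))
  res <- consensus_cluster(X, k_range = 2:5, reps = 60, seed = 3)
  expect_equal(select_k_delta_area(res)$k, 2)
  # the consensus CDF is a valid, non-decreasing distribution for every K
  for (k in as.character(2:5)) {
    cdf <- roiomics:::consensus_cdf_area(res$consensus[[k]])
    expect_true(all(diff(cdf$y) >= 0))
  }
})

test_that("consensus assignments are equivariant under column permutation", {
  blobs <- make_blobs(n_per = 4, seed = 21)
  perm <- sample(ncol(blobs$X))
  res1 <- consensus_cluster(blobs$X, k_range = 2, reps = 50, seed = 5)
  res2 <- consensus_cluster(blobs$X[, perm], k_range = 2, reps = 50, seed = 5)
  # same partition of the same items, independent of column order
  expect_equal(adjusted_rand_index(res1$labels[["2"]][perm], res2$labels[["2"]]), 1)
})

test_that("seeded k-means finds separated blobs and honors k = 1", {
  blobs <- make_blobs(n_per = 6, seed = 10)
  km <- kmeans_seeded(t(blobs$X), k = 2, seed = 4)
  expect_equal(adjusted_rand_index(km$labels, blobs$labels), 1)
  km1 <- kmeans_seeded(t(blobs$X), k = 1, seed = 4)
  expect_equal(as.numeric(km1$centers), unname(colMeans(t(blobs$X))),
               tolerance = 1e-12)
  expect_error(kmeans_seeded(t(blobs$X), k = 99, seed = 1), "exceeds")
})

test_that("the adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  set.seed(17)
  for (i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 1)), 1)
})
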