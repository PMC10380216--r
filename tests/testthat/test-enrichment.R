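test_that("BH adjustment reproduces the step-up hand computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(0.2), 0.2)
  p <- runif(50)
  expect_setequal(round(bh_adjust(p), 12), round(bh_adjust(rev(p)), 12))
  expect_error(bh_adjust(c(0.5, 1.2)), "outside")
})

test_that("ORA p-values equal the enumerated hypergeometric upper tail", {
  universe <- paste0("g", 1:10)
  hits <- paste0("g", 1:5)
  gene_set <- paste0("g", c(1:4))
  rec <- fisher_ora(hits, gene_set, universe)   # N=10, K=4, n=5, k=4
  expect_equal(rec$p, 6 / 252, tolerance = 1e-12)
  expect_equal(rec$p, oracle_hyper_upper(4, 4, 10, 5), tolerance = 1e-12)

  # k = 0 with a non-empty set: upper tail from 0 is 1
  rec0 <- fisher_ora(paste0("g", 9:10), paste0("g", 1:4), universe)
  expect_equal(rec0$p, 1)
  expect_warning(recd <- fisher_ora(hits, c("zz1", "zz2"), universe), "disjoint")
  expect_equal(recd$p, 1)
  expect_error(fisher_ora(hits, gene_set, character(0)), "empty universe")
  expect_error(fisher_ora(c("not_in_universe"), gene_set, universe), "subset")

  # random instances against the enumeration oracle
  set.seed(12)
  for (i in 1:25) {
    N <- sample(15:60, 1)
    uni <- paste0("u", seq_len(N))
    K <- sample(2:10, 1); n <- sample(2:12, 1)
    gs <- sample(uni, K); h <- sample(uni, n)
    k <- length(intersect(gs, h))
    expect_equal(fisher_ora(h, gs, uni)$p, oracle_hyper_upper(k, K, N, n),
                 tolerance = 1e-12)
  }
})

test_that("the GSEA ranking metric multiplies coefficients by -log10 p", {
  expect_equal(rank_metric(1, 0.1), 1)
  expect_equal(rank_metric(3, 1), 0)
  expect_equal(rank_metric(matrix(c(2, 4), 1, 2), 0.01), 6)  # mean coef x 2
  expect_warning(out <- rank_metric(2, 0), "clamped")
  expect_true(is.finite(out))
  expect_error(rank_metric(1, 1.5), "outside")
})

test_that("the enrichment score matches a brute-force running sum", {
  set.seed(6)
  scores <- setNames(rnorm(10), paste0("g", 1:10))
  set3 <- c("g2", "g5", "g9")
  res <- preranked_gsea(scores, list(s = set3), n_perm = 50, seed = 1)
  expect_equal(res$es, oracle_gsea_es(scores, set3), tolerance = 1e-12)

  # larger random instances, several weights
  for (i in 1:10) {
    sc <- setNames(rnorm(60), paste0("f", 1:60))
    st <- sample(names(sc), 8)
    for (w in c(0, 1)) {
      got <- preranked_gsea(sc, list(x = st), weight = w, n_perm = 10, seed = 2)$es
      expect_equal(got, oracle_gsea_es(sc, st, w), tolerance = 1e-12)
    }
  }
})

test_that("GSEA direction, antisymmetry and permutation p behave as expected", {
  set.seed(44)
  scores <- setNames(sort(rnorm(100), decreasing = TRUE), paste0("g", 1:100))
  top5 <- names(scores)[1:5]
  res <- preranked_gsea(scores, list(top = top5), n_perm = 1000, seed = 3)
  expect_gt(res$es, 0)
  expect_lte(res$p, 0.05)
  expect_equal(sign(res$nes), sign(res$es))
  expect_gte(res$adj_p, res$p)

  rev_scores <- -scores
  res_rev <- preranked_gsea(rev_scores, list(top = top5), n_perm = 10, seed = 3)
  expect_equal(res_rev$es, -res$es, tolerance = 1e-12)

  # relabeling features (bijectively) leaves the ES unchanged
  relabeled <- setNames(scores, paste0("h", 1:100))
  res_rel <- preranked_gsea(relabeled, list(top = paste0("h", 1:5)),
                            n_perm = 10, seed = 3)
  expect_equal(res_rel$es, res$es, tolerance = 1e-12)

  # no overlap: reported with NA statistics rather than dropped silently
  res_no <- preranked_gsea(scores, list(none = c("zz")), n_perm = 10, seed = 1)
  expect_true(is.na(res_no$es))
})

test_that("collection-level ORA honors size bounds and BH ordering", {
  universe <- paste0("g", 1:50)
  hits <- paste0("g", 1:10)
  coll <- list(good = paste0("g", 1:8), tiny = "g1",
               off = paste0("g", 40:50))
  res <- ora_collection(hits, coll, universe, min_size = 2)
  expect_false("tiny" %in% res$set)
  expect_true(all(res$adj_p >= res$p))
  expect_equal(res$set[1], "good")
})
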