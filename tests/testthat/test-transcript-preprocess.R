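make_probe_matrix <- function(values_by_probe, n_roi = 6) {
  m <- do.call(rbind, lapply(values_by_probe, function(v) rep(v, n_roi)))
  rownames(m) <- paste0("geneA_p", seq_along(values_by_probe))
  colnames(m) <- paste0("roi", seq_len(n_roi))
  m
}

test_that("probe QC flags low-ratio probes and leaves clean genes alone", {
  clean <- make_probe_matrix(list(10, 10, 10, 10, 10))
  expect_equal(nrow(detect_outlier_probes(clean, rep("geneA", 5))), 0)

  # probe at 5% of the gene geometric mean with threshold 0.1: rule (a)
  m <- make_probe_matrix(list(100, 100, 100, 100, 100))
  gm_others <- 100
  m[5, ] <- 0.05 * gm_others  # well below 0.1 x gene GM even after pooling
  flags <- detect_outlier_probes(m, rep("geneA", 5), ratio_threshold = 0.1)
  expect_equal(flags$probe_id, "geneA_p5")
  expect_equal(flags$reason, "low_ratio")
})

test_that("probe QC flags Grubbs outliers present in enough ROIs", {
  set.seed(4)
  n_roi <- 10
  m <- matrix(rlnorm(5 * n_roi, log(100), 0.05), 5, n_roi,
              dimnames = list(paste0("geneA_p", 1:5), paste0("roi", 1:n_roi)))
  m[3, 1:5] <- m[3, 1:5] * 50   # inflated 50x in half the ROIs
  flags <- detect_outlier_probes(m, rep("geneA", 5), grubbs_alpha = 0.01)
  expect_true("geneA_p3" %in% flags$probe_id)
  expect_true(all(flags$reason[flags$probe_id == "geneA_p3"] == "grubbs"))
  # oracle: tabulated two-sided Grubbs critical value for n = 5, alpha = .01
  t2 <- qt(0.01 / 10, df = 3, lower.tail = FALSE)
  expect_equal((4 / sqrt(5)) * sqrt(t2^2 / (3 + t2^2)), 1.764, tolerance = 1e-3)

  expect_warning(detect_outlier_probes(matrix(1:4, 1), "solo"), "single probe")
})

test_that("gene collapse takes the geometric mean of unflagged probes", {
  m <- matrix(c(2, 8), 2, 3, dimnames = list(c("gA_p1", "gA_p2"), paste0("r", 1:3)))
  expect_equal(unname(collapse_to_gene_counts(m, c("gA", "gA"))[1, ]), rep(4, 3))

  m2 <- rbind(m, gA_p3 = rep(1000, 3))
  flags <- data.frame(probe_id = "gA_p3", gene = "gA", reason = "low_ratio")
  expect_equal(unname(collapse_to_gene_counts(m2, rep("gA", 3), flags)[1, ]),
               rep(4, 3))
  flags_all <- data.frame(probe_id = rownames(m2), gene = "gA", reason = "x")
  expect_error(collapse_to_gene_counts(m2, rep("gA", 3), flags_all), "gA")

  const <- matrix(7, 4, 2, dimnames = list(paste0("g_p", 1:4), c("r1", "r2")))
  expect_equal(unname(collapse_to_gene_counts(const, rep("g", 4))[1, ]), c(7, 7))
})

test_that("LOQ equals GM x GSD^2 with population log-SD", {
  neg <- matrix(c(2, 8), 2, 1, dimnames = list(c("n1", "n2"), "roi1"))
  expect_equal(unname(compute_loq(neg)), 16)
  neg4 <- matrix(4, 4, 2, dimnames = list(paste0("n", 1:4), c("r1", "r2")))
  expect_equal(unname(compute_loq(neg4)), c(4, 4))
  negc <- matrix(c(5, 5, 5), 3, 1, dimnames = list(paste0("n", 1:3), "r"))
  expect_equal(unname(compute_loq(negc)), 5)  # GSD = 1
})

test_that("Q3 normalization aligns third quartiles on their geometric mean", {
  set.seed(2)
  base <- rlnorm(200, 5, 1)
  m <- cbind(r1 = base, r2 = base * 4)
  rownames(m) <- paste0("g", 1:200)
  res <- q3_normalize(m)
  expect_equal(res$report$q3[2] / res$report$q3[1], 4, tolerance = 1e-12)
  expect_equal(res$report$factor, c(2, 0.5), tolerance = 1e-12)
  # identical ROIs: factors 1, matrix unchanged
  m2 <- cbind(r1 = base, r2 = base)
  res2 <- q3_normalize(m2)
  expect_equal(res2$report$factor, c(1, 1))
  expect_equal(res2$normalized, m2)
  # scaling one ROI by c divides its factor by c (up to the shared GM shift)
  m3 <- m; m3[, 2] <- m3[, 2] * 8
  res3 <- q3_normalize(m3)
  expect_equal(res3$report$factor[2] / res3$report$factor[1] ,
               (res$report$factor[2] / res$report$factor[1]) / 8,
               tolerance = 1e-12)
  # normalization target: GM of post-normalization Q3s equals GM of input Q3s
  q3_after <- apply(res$normalized, 2, quantile, 0.75, names = FALSE)
  expect_equal(exp(mean(log(q3_after))), exp(mean(log(res$report$q3))),
               tolerance = 1e-9)
})

test_that("rank order within each ROI survives Q3 normalization", {
  co <- small_cohort()
  pre <- preprocess_transcripts(co$probe_counts)
  fm <- co$probe_counts$feature_meta
  raw <- collapse_to_gene_counts(
    co$probe_counts$values[!fm$is_negative, ], fm$symbol[!fm$is_negative],
    pre$flags)
  norm <- pre$normalized$values
  shared <- intersect(rownames(raw), rownames(norm))
  for (j in sample(ncol(norm), 5))
    expect_equal(rank(norm[shared, j]), rank(raw[shared, j]))
})

test_that("re-running QC on collapsed counts flags nothing new", {
  co <- small_cohort()
  pre <- preprocess_transcripts(co$probe_counts)
  genes <- pre$normalized$values
  # each collapsed gene is a single "probe": nothing to flag
  expect_warning(
    flags2 <- detect_outlier_probes(genes, rownames(genes)),
    "single probe")
  expect_equal(nrow(flags2), 0)
})
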