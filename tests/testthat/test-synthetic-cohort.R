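test_that("same seed reproduces the cohort exactly", {
  a <- generate_cohort(small_config(seed = 11L))
  b <- generate_cohort(small_config(seed = 11L))
  expect_identical(a$probe_counts$values, b$probe_counts$values)
  expect_identical(a$protein_intensities$values, b$protein_intensities$values)
  expect_identical(a$roi_annotations, b$roi_annotations)
  expect_identical(a$survival, b$survival)
  expect_identical(a$truth$true_cell_fractions, b$truth$true_cell_fractions)
})

test_that("invalid configurations are rejected with the field named", {
  expect_error(cohort_config(n_patients = 0), "n_patients")
  expect_error(cohort_config(nb_dispersion = -1), "nb_dispersion")
  expect_error(cohort_config(prois_per_patient = c(4, 2)), "prois_per_patient")
  expect_error(cohort_config(mnar_logistic_slope = 0), "mnar_logistic_slope")
  expect_error(cohort_config(shared_symbols = 999), "shared_symbols")
})

test_that("null configuration shows no tumor-vs-NAT shift", {
  cfg <- small_config(seed = 21L)
  cfg$tumor_effect_log2fc <- 0
  cfg$n_planted_de <- 0
  cfg$n_planted_immune <- 0
  cfg$n_planted_variable <- 0
  co <- generate_cohort(cfg)
  pre <- preprocess_transcripts(co$probe_counts)
  ann <- pre$normalized$roi_meta
  lg <- log2(pre$normalized$values + 1)
  diff <- rowMeans(lg[, ann$tissue == "tumor"]) - rowMeans(lg[, ann$tissue == "NAT"])
  expect_lt(abs(mean(diff)), 0.15)
})

test_that("planted DE genes carry the configured log2 fold change", {
  co <- test_cohort()   # tumor_effect_log2fc = 1, 20 planted genes
  pre <- preprocess_transcripts(co$probe_counts)
  ann <- pre$normalized$roi_meta
  lg <- log2(pre$normalized$values + 1)
  truth <- co$truth$planted_de_genes
  realized <- rowMeans(lg[truth$feature, ann$tissue == "tumor"]) -
    rowMeans(lg[truth$feature, ann$tissue == "NAT"])
  expect_true(all(abs(realized - truth$true_log2fc) < 0.3))
})

test_that("NAT ROIs never carry planted tumor effects", {
  cfg0 <- small_config(seed = 33L)
  cfg0$tumor_effect_log2fc <- 0
  cfg2 <- small_config(seed = 33L)
  cfg2$tumor_effect_log2fc <- 2
  co0 <- generate_cohort(cfg0)
  co2 <- generate_cohort(cfg2)
  nat <- co0$roi_annotations$roi_id[co0$roi_annotations$roi_kind == "tROI" &
                                      co0$roi_annotations$tissue == "NAT"]
  tum <- setdiff(colnames(co0$probe_counts$values), nat)
  planted <- co2$truth$planted_de_genes$feature
  probes <- co2$probe_counts$feature_meta$feature_id[
    co2$probe_counts$feature_meta$symbol %in% planted &
      !co2$probe_counts$feature_meta$is_negative]
  # same seed, planted effect 2 vs 0: the NAT group mean of the planted
  # genes is unchanged (up to NB sampling noise), the tumor group mean moves
  l0 <- log2(co0$probe_counts$values[probes, ] + 1)
  l2 <- log2(co2$probe_counts$values[probes, ] + 1)
  expect_lt(abs(mean(l2[, nat]) - mean(l0[, nat])), 0.1)
  up <- probes[rep(co2$truth$planted_de_genes$true_log2fc > 0,
                   each = co2$config$probes_per_gene)]
  expect_gt(mean(l2[up, tum]) - mean(l0[up, tum]), 1)
})

test_that("every planted feature exists in the generated matrices", {
  co <- small_cohort()
  syms <- co$probe_counts$feature_meta$symbol
  expect_true(all(co$truth$planted_de_genes$feature %in% syms))
  expect_true(all(co$truth$planted_variable_genes$feature %in% syms))
  prots <- rownames(co$protein_intensities$values)
  expect_true(all(co$truth$planted_de_proteins$feature %in% prots))
  expect_true(all(co$truth$planted_correlated_pairs$symbol %in% prots))
  expect_true(all(co$truth$true_cell_fractions >= 0))
})

test_that("tROI parents stay within the same case", {
  ann <- test_cohort()$roi_annotations
  t <- ann[ann$roi_kind == "tROI" & !is.na(ann$parent_proi), ]
  parent_case <- ann$case_id[match(t$parent_proi, ann$roi_id)]
  expect_true(all(parent_case == t$case_id))
})

test_that("MNAR injection is seed-stable, intensity-dependent and vanishes in easy regimes", {
  set.seed(1)
  m <- matrix(rnorm(10000, 25, 3), 100, 100,
              dimnames = list(paste0("p", 1:100), paste0("r", 1:100)))
  # midpoint far below all values, steep slope: nothing goes missing
  none <- inject_mnar_missingness(m, midpoint = min(m) - 10, slope = 50, seed = 2)
  expect_false(anyNA(none))
  a <- inject_mnar_missingness(m, midpoint = 25, slope = 1, seed = 3)
  b <- inject_mnar_missingness(m, midpoint = 25, slope = 1, seed = 3)
  expect_identical(is.na(a), is.na(b))
  # binned missingness rate non-increasing in intensity
  bins <- cut(m, breaks = quantile(m, probs = seq(0, 1, 0.1)), include.lowest = TRUE)
  rate <- tapply(as.vector(is.na(a)), bins, mean)
  expect_true(all(diff(rate) <= 0.02))  # monotone up to binomial noise
  expect_error(inject_mnar_missingness(m, Inf, 1, 1), "non-finite")
  expect_error(inject_mnar_missingness(m, 25, -1, 1), "positive")
})

test_that("midpoint calibration hits a requested overall missingness", {
  co <- small_cohort()
  complete <- co$truth$complete_protein
  for (target in c(0.15, 0.4)) {
    mid <- calibrate_mnar_midpoint(complete, target, slope = 1.2)
    got <- mean(is.na(inject_mnar_missingness(complete, mid, 1.2, seed = 9)))
    expect_lt(abs(got - target), 0.05)
  }
})

test_that("planted cross-omic pairs correlate near the target after aggregation", {
  co <- test_cohort()
  pre <- preprocess_transcripts(co$probe_counts)
  ann <- co$roi_annotations
  agg <- aggregate_troi_to_proi(log2(pre$normalized$values + 1), ann)
  pairs <- co$truth$planted_correlated_pairs
  prot <- co$truth$complete_protein  # correlation is a property of the signal, pre-missingness
  shared_prois <- intersect(colnames(agg), colnames(prot))
  r <- vapply(pairs$symbol, function(s)
    cor(agg[s, shared_prois], prot[s, shared_prois]), numeric(1))
  expect_lt(abs(mean(r) - pairs$target_r[1]), 0.15)
})
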