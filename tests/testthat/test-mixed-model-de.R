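# Construct a small AnnotatedMatrix with explicit tissue/score structure.
make_de_am <- function(values, case_id, tissue, extra = list()) {
  meta <- data.frame(roi_id = colnames(values), case_id = case_id,
                     roi_kind = "tROI", tissue = tissue,
                     stringsAsFactors = FALSE)
  for (nm in names(extra)) meta[[nm]] <- extra[[nm]]
  annotated_matrix(values, meta)
}

test_that("the mixed model collapses to OLS when patient variance is zero", {
  # scan seeds for a dataset whose REML variance estimate hits the zero
  # boundary (singular fit): the model must then fall back to exact OLS
  found <- FALSE
  for (s in 1:20) {
    set.seed(s)
    n <- 120
    x <- rnorm(n)
    pat <- rep(paste0("P", 1:6), each = 20)
    y <- 1 + 0.8 * x + rnorm(n, 0, 0.5)  # no patient effect at all
    fit <- fit_lmm_feature(y, x, pat)
    ols <- summary(lm(y ~ x))$coefficients
    expect_equal(fit$coefficient, ols["x", "Estimate"], tolerance = 2e-2)
    if (fit$fallback_ols) {
      found <- TRUE
      expect_equal(fit$coefficient, ols["x", "Estimate"], tolerance = 1e-6)
      expect_equal(fit$se, ols["x", "Std. Error"], tolerance = 1e-6)
      break
    }
  }
  expect_true(found)
  expect_error(fit_lmm_feature(y, rep(1, n), pat), "constant")
  expect_error(fit_lmm_feature(y, x, rep("P1", n)), "2 patients")
})

test_that("Wald test holds its nominal size under the null", {
  set.seed(77)
  n_pat <- 20
  per <- 10
  pat <- rep(paste0("P", seq_len(n_pat)), each = per)
  reps <- 1000
  pvals <- vapply(seq_len(reps), function(i) {
    u <- rnorm(n_pat, 0, 0.5)[rep(seq_len(n_pat), each = per)]
    y <- u + rnorm(n_pat * per)
    x <- rnorm(n_pat * per)
    fit_lmm_feature(y, x, pat)$p
  }, numeric(1))
  alpha <- mean(pvals < 0.05)
  expect_gte(alpha, 0.03)
  expect_lte(alpha, 0.07)
})

test_that("confidence intervals cover a planted slope at the nominal rate", {
  set.seed(5)
  n_pat <- 15
  per <- 8
  pat <- rep(paste0("P", seq_len(n_pat)), each = per)
  hits <- vapply(seq_len(500), function(i) {
    u <- rnorm(n_pat, 0, 0.5)[rep(seq_len(n_pat), each = per)]
    x <- rnorm(n_pat * per)
    y <- u + 1.0 * x + rnorm(n_pat * per)
    f <- fit_lmm_feature(y, x, pat)
    abs(f$coefficient - 1.0) <= qnorm(0.975) * f$se
  }, logical(1))
  expect_gte(mean(hits), 0.93)
})

test_that("tumor-vs-NAT applies the FC + BH rule and recovers planted genes", {
  cfg <- cohort_config(seed = 19L, tumor_effect_log2fc = 2)  # 4-fold planted genes
  co <- generate_cohort(cfg)
  pre <- preprocess_transcripts(co$probe_counts)
  de <- tumor_vs_nat(pre$normalized, log2_transform = TRUE)
  truth <- co$truth$planted_de_genes$feature
  called <- de$feature[de$significant]
  sensitivity <- mean(truth %in% called)
  false_calls <- setdiff(called, truth)
  fdr <- if (length(called) > 0) length(false_calls) / length(called) else 0
  expect_gte(sensitivity, 0.9)
  expect_lte(fdr, 0.1)
  # swapping the group labels flips every coefficient
  am2 <- pre$normalized
  am2$roi_meta$tissue <- ifelse(am2$roi_meta$tissue == "tumor", "NAT", "tumor")
  de2 <- tumor_vs_nat(am2, log2_transform = TRUE)
  expect_equal(de2$coefficient, -de$coefficient, tolerance = 1e-6)
})

test_that("the 1.5-fold-change gate overrides even tiny p-values", {
  set.seed(30)
  n_pat <- 6
  pat <- rep(paste0("P", 1:n_pat), each = 8)
  tissue <- rep(rep(c("tumor", "NAT"), each = 4), n_pat)
  # log2 FC of exactly log2(1.4) with minuscule noise: p tiny, FC below gate
  y <- ifelse(tissue == "tumor", log2(1.4), 0) + rnorm(length(pat), 0, 0.01)
  v <- matrix(2^y, 1, length(y),
              dimnames = list("f_small", paste0("r", seq_along(y))))
  am <- make_de_am(v, pat, tissue)
  de <- tumor_vs_nat(am, log2_transform = FALSE)
  # fit on the stored (already log2-like) values
  de <- tumor_vs_nat(make_de_am(matrix(y, 1, length(y),
                                       dimnames = dimnames(v)), pat, tissue))
  expect_lt(de$p, 1e-6)
  expect_false(de$significant)
})

test_that("patients lacking a tissue type contribute no rows", {
  set.seed(31)
  pat <- c(rep("P1", 8), rep("P2", 8), rep("P3", 6))
  tissue <- c(rep(c("tumor", "NAT"), 4), rep(c("tumor", "NAT"), 4),
              rep("tumor", 6))  # P3 has tumor only
  v <- matrix(rnorm(3 * 22, 10), 3, 22,
              dimnames = list(paste0("f", 1:3), paste0("r", 1:22)))
  # plant an enormous P3-specific shift: it must not influence the estimate
  v2 <- v
  v2[, pat == "P3"] <- v2[, pat == "P3"] + 100
  de_a <- tumor_vs_nat(make_de_am(v, pat, tissue))
  de_b <- tumor_vs_nat(make_de_am(v2, pat, tissue))
  expect_equal(de_a$coefficient, de_b$coefficient, tolerance = 1e-8)
  expect_equal(unique(de_a$n_patients), 2)
  expect_error(tumor_vs_nat(make_de_am(v[, 1:6, drop = FALSE], pat[1:6],
                                       rep("tumor", 6))),
               "fewer than 2 patients")
})

test_that("ordinal trend significance needs monotone means, span and adjusted p", {
  set.seed(40)
  n_pat <- 5
  # 5 patients x 6 ROIs, scores 1,1,2,2,3,3 per patient
  pat <- rep(paste0("P", 1:n_pat), each = 6)
  score <- rep(c(1, 1, 2, 2, 3, 3), n_pat)
  n <- length(pat)
  mk <- function(nm, level_means) {
    y <- level_means[score] + rnorm(n, 0, 0.05)
    matrix(y, 1, n, dimnames = list(nm, paste0("r", 1:n)))
  }
  base <- rbind(mk("up", c(5, 6, 7)), mk("wiggle", c(5, 7, 6)),
                mk("flat", c(5, 5.2, 5.4)))
  am <- make_de_am(base, pat, rep("tumor", n), extra = list(immune_score = score))
  de <- ordinal_trend_de(am, "immune_score", "up")
  expect_true(de$significant[de$feature == "up"])
  expect_false(de$significant[de$feature == "wiggle"])   # non-monotone
  expect_false(de$significant[de$feature == "flat"])     # span 0.4 < log2(1.5)
  expect_true(all(de$monotone[de$feature == "up"]))
  expect_lt(de$p[de$feature == "wiggle"], 0.05)  # p alone would have called it
})

test_that("singleton ordinal levels and NAT ROIs are excluded before fitting", {
  set.seed(41)
  pat <- rep(paste0("P", 1:4), each = 7)
  score <- rep(c(0, 1, 1, 2, 2, 3, 3), 4)
  score[score == 0] <- NA  # NAT gets no score
  tissue <- ifelse(is.na(score), "NAT", "tumor")
  score[seq_along(score) == 2] <- score[2]
  n <- length(pat)
  v <- matrix(rnorm(n, 10), 1, n, dimnames = list("f", paste0("r", 1:n)))
  am <- make_de_am(v, pat, tissue, extra = list(mucin_score = score))
  # make level 1 a singleton: drop all other level-1 ROIs to NAT
  lvl1 <- which(!is.na(score) & score == 1)
  am$roi_meta$mucin_score[lvl1[-1]] <- NA
  am$roi_meta$tissue[lvl1[-1]] <- "NAT"
  de <- ordinal_trend_de(am, "mucin_score", "up")
  expect_equal(unique(de$levels_used), "2,3")
  am$roi_meta$mucin_score[am$roi_meta$mucin_score %in% c(2, 3)] <- 2
  expect_error(ordinal_trend_de(am, "mucin_score", "up"), "one ordinal level")
})

test_that("continuous-covariate DE recovers planted TIL slopes and controls the null", {
  co <- test_cohort()
  pp <- preprocess_proteins(co$protein_intensities, seed = 2)
  de <- continuous_covariate_de(pp$processed, "til_pct")
  truth <- co$truth$planted_til_proteins
  measured <- intersect(truth, de$feature)
  expect_gte(mean(de$significant[match(measured, de$feature)]), 0.8)
  # dedicated null: 1000 features, 20 patients, no covariate effect
  set.seed(55)
  n_pat <- 20; per <- 10
  pat <- rep(sprintf("P%02d", seq_len(n_pat)), each = per)
  til <- rep(runif(n_pat, 5, 40), each = per)
  u <- rnorm(n_pat, 0, 0.5)[rep(seq_len(n_pat), each = per)]
  null_m <- t(vapply(seq_len(1000), function(i) u + rnorm(n_pat * per),
                     numeric(n_pat * per)))
  dimnames(null_m) <- list(sprintf("f%04d", 1:1000),
                           sprintf("r%03d", seq_len(n_pat * per)))
  am_null <- make_de_am(null_m, pat, rep("tumor", n_pat * per),
                        extra = list(til_pct = til))
  de_null <- continuous_covariate_de(am_null, "til_pct")
  expect_lte(mean(de_null$p < 0.05), 0.07)
  # rescaling the covariate leaves p untouched and scales the coefficient
  am2 <- pp$processed
  am2$roi_meta$til_pct <- am2$roi_meta$til_pct * 100
  de2 <- continuous_covariate_de(am2, "til_pct")
  expect_equal(de2$p, de$p, tolerance = 1e-6)
  expect_equal(de2$coefficient * 100, de$coefficient, tolerance = 1e-6)
})

test_that("BH significance calls are invariant to feature order", {
  co <- small_cohort()
  pre <- preprocess_transcripts(co$probe_counts)
  de <- tumor_vs_nat(pre$normalized, log2_transform = TRUE)
  am_shuffled <- am_subset(pre$normalized,
                           features = rev(rownames(pre$normalized$values)))
  de_r <- tumor_vs_nat(am_shuffled, log2_transform = TRUE)
  expect_setequal(de$feature[de$significant], de_r$feature[de_r$significant])
})
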