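# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

# A moderate synthetic cohort used by the planted-recovery tests.
test_cohort <- function() {
  if (is.null(.fixture_env$cohort)) {
    .fixture_env$cohort <- generate_cohort(cohort_config(seed = 42L))
  }
  .fixture_env$cohort
}

# A small cohort for cheap structural tests.
small_cohort <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- generate_cohort(small_config(seed = 7L))
  }
  .fixture_env$small
}

small_config <- function(seed = 7L) {
  cohort_config(n_genes = 80, n_proteins = 80, shared_symbols = 40,
                n_planted_de = 8, n_planted_immune = 6, n_planted_variable = 6,
                n_planted_correlated = 8, n_decon_genes = 30, seed = seed)
}

# --- independent oracles -------------------------------------------------

# Brute-force GSEA running sum, written directly from the definition.
oracle_gsea_es <- function(scores, set, weight = 1) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  feats <- names(s)
  in_set <- feats %in% set
  N <- length(s)
  n <- sum(in_set)
  p_hit <- 0
  p_miss <- 0
  denom <- sum(abs(s[in_set])^weight)
  best <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) p_hit <- p_hit + abs(s[i])^weight / denom
    else p_miss <- p_miss + 1 / (N - n)
    dev <- p_hit - p_miss
    if (abs(dev) > abs(best)) best <- dev
  }
  unname(best)
}

# Exhaustive best 2-medoid solution by total cost.
oracle_best_2medoids <- function(D) {
  n <- nrow(D)
  best_cost <- Inf
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    cost <- sum(pmin(D[, i], D[, j]))
    if (cost < best_cost) {
      best_cost <- cost
      best <- c(i, j)
    }
  }
  list(medoids = best, cost = best_cost)
}

# Hypergeometric upper tail by direct enumeration of the mass function.
oracle_hyper_upper <- function(k, K, N, n) {
  ks <- k:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# Grid-maximized Cox partial likelihood (Breslow form; no ties in use).
oracle_cox_beta_grid <- function(time, event, x, grid = seq(-5, 5, by = 1e-3)) {
  loglik <- vapply(grid, function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- time >= time[i]
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }, numeric(1))
  grid[which.max(loglik)]
}

# Two well-separated blobs (columns = items) with distinct feature
# PATTERNS, so they separate under Pearson correlation distance
# (a pure mean offset would vanish under per-feature z-scoring).
make_blobs <- function(n_per = 5, n_feat = 30, pattern_sd = 3, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(n_feat * 2, sd = pattern_sd), n_feat, 2)
  X <- cbind(centers[, 1] + matrix(rnorm(n_feat * n_per, 0, 0.1), n_feat),
             centers[, 2] + matrix(rnorm(n_feat * n_per, 0, 0.1), n_feat))
  colnames(X) <- paste0("item", seq_len(2 * n_per))
  list(X = X, labels = rep(1:2, each = n_per))
}

# z-score matrix rows (as consensus_cluster does internally)
scale_rows <- function(X) {
  s <- apply(X, 1, sd)
  (X[s > 0, , drop = FALSE] - rowMeans(X[s > 0, , drop = FALSE])) / s[s > 0]
}
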