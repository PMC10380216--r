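#' Pearson correlation distance between matrix columns
#'
#' D[i, j] = 1 - r(column i, column j), in [0, 2] with a zero diagonal.
#'
#' @param X numeric matrix, features x items (items = ROIs in columns).
#' @return symmetric distance matrix, items x items.
#' @export
pearson_distance <- function(X) {
  stopifnot(is.matrix(X), ncol(X) >= 2)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  D <- 1 - stats::cor(X)
  diag(D) <- 0
  D
}

#' Partitioning around medoids on a precomputed distance matrix
#'
#' BUILD plus SWAP phases (via \code{cluster::pam}); deterministic for a
#' fixed distance matrix.
#'
#' @param D square symmetric distance matrix with zero diagonal.
#' @param k number of clusters, 1 <= k <= nrow(D).
#' @return list with \code{labels} (integer vector in 1..k), \code{medoids}
#'   (indices) and \code{cost} (sum of distances to assigned medoids).
#' @export
pam_cluster <- function(D, k) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (k > n) stop("k = ", k, " exceeds the number of items (", n, ")")
  if (k == n) {
    return(list(labels = seq_len(n), medoids = seq_len(n), cost = 0))
  }
  fit <- cluster::pam(stats::as.dist(D), k = k, diss = TRUE,
                      nstart = 1, cluster.only = FALSE)
  med <- if (is.numeric(fit$id.med)) fit$id.med else match(fit$medoids, rownames(D))
  labels <- as.integer(fit$clustering)
  cost <- sum(vapply(seq_len(n), function(i) D[i, med[labels[i]]], numeric(1)))
  list(labels = labels, medoids = med, cost = cost)
}

#' Bootstrap consensus clustering with PAM on Pearson distance
#'
#' The expression matrix is z-scored per feature, then repeatedly
#' subsampled: each replicate keeps a fraction \code{p_item} of the items
#' (columns) and \code{p_feature} of the features (rows), clusters the
#' subsample with PAM on Pearson distance, and accumulates co-clustering
#' evidence. The consensus matrix entry M[i, j] is the number of times
#' items i and j were clustered together divided by the number of times
#' they were subsampled together (0/0 treated as 0). Final labels per K
#' come from complete-linkage hierarchical clustering of 1 - M cut at K.
#'
#' @param X features x items matrix (no missing values).
#' @param k_range candidate cluster numbers (default 2:10).
#' @param reps number of bootstrap replicates per K (default 1000).
#' @param p_item,p_feature subsampling fractions (default 0.8).
#' @param seed integer seed driving all replicate subsamples.
#' @return object of class \code{ConsensusResult}: per-K consensus matrices
#'   and labels, the parameters, and the item names.
#' @export
consensus_cluster <- function(X, k_range = 2:10, reps = 1000,
                              p_item = 0.8, p_feature = 0.8, seed = 0L) {
  stopifnot(is.matrix(X), ncol(X) >= 3, all(k_range >= 2),
            p_item > 0, p_item <= 1, p_feature > 0, p_feature <= 1)
  k_range <- sort(unique(as.integer(k_range)))
  n <- ncol(X)
  # z-score each feature; drop constant features (their z-score is undefined)
  sds <- apply(X, 1, stats::sd)
  Z <- (X[sds > 0, , drop = FALSE] - rowMeans(X[sds > 0, , drop = FALSE])) / sds[sds > 0]
  nf <- nrow(Z)
  n_item <- max(2L, floor(p_item * n))
  n_feat <- max(2L, floor(p_feature * nf))
  consensus <- list()
  labels <- list()
  with_seed(seed, {
    for (k in k_range) {
      co <- matrix(0, n, n)
      tog <- matrix(0, n, n)
      for (r in seq_len(reps)) {
        items <- sort(sample.int(n, n_item))
        feats <- sample.int(nf, n_feat)
        if (length(items) < k) {
          warning("replicate with fewer items than k = ", k, " discarded")
          next
        }
        sub <- Z[feats, items, drop = FALSE]
        sds_sub <- apply(sub, 2, stats::sd)
        if (any(sds_sub == 0)) next  # degenerate subsample, cannot form Pearson distance
        D <- pearson_distance(sub)
        lab <- pam_cluster(D, k)$labels
        tog[items, items] <- tog[items, items] + 1
        same <- outer(lab, lab, `==`)
        co[items, items] <- co[items, items] + same
      }
      M <- ifelse(tog > 0, co / tog, 0)
      diag(M) <- 1
      dimnames(M) <- list(colnames(X), colnames(X))
      hc <- stats::hclust(stats::as.dist(1 - M), method = "complete")
      lab_k <- stats::cutree(hc, k = k)
      consensus[[as.character(k)]] <- M
      labels[[as.character(k)]] <- lab_k
    }
  })
  structure(list(consensus = consensus, labels = labels, k_range = k_range,
                 items = colnames(X),
                 params = list(reps = reps, p_item = p_item,
                               p_feature = p_feature, seed = seed)),
            class = "ConsensusResult")
}

#' @export
print.ConsensusResult <- function(x, ...) {
  cat(sprintf("ConsensusResult: %d items, K in {%s}, %d replicates\n",
              length(x$items), paste(x$k_range, collapse = ", "),
              x$params$reps))
  invisible(x)
}

# Empirical CDF evaluated at sorted unique consensus values, and the area
# under it, for the off-diagonal entries of one consensus matrix.
consensus_cdf_area <- function(M) {
  v <- sort(M[upper.tri(M)])
  cdf_x <- sort(unique(c(0, v, 1)))
  cdf_y <- stats::ecdf(v)(cdf_x)
  area <- sum(diff(cdf_x) * cdf_y[-length(cdf_y)])
  list(x = cdf_x, y = cdf_y, area = area)
}

#' Select the number of clusters from the consensus CDFs
#'
#' Mechanizes the visual elbow inspection of consensus CDF plots. Per K,
#' the empirical CDF of off-diagonal consensus values and its area are
#' computed; a K (beyond the smallest) is a candidate when its relative
#' area increase over the previous K is at least \code{threshold}. Because
#' resampled partitions of even structureless data keep gaining CDF area
#' with K, candidates are additionally required to be unambiguous: the
#' proportion of ambiguous clustering (PAC; off-diagonal consensus values
#' inside \code{pac_range}) must not exceed \code{pac_max}. The chosen K is
#' the largest such candidate, falling back to the smallest K when no
#' candidate qualifies (structureless data).
#'
#' @param result a \code{ConsensusResult} with at least two K values.
#' @param threshold minimum relative delta-area (default 0.05).
#' @param pac_range interval of consensus values counted as ambiguous
#'   (default c(0.1, 0.9)).
#' @param pac_max maximum tolerated PAC for a candidate K (default 0.1).
#' @return list with \code{k} (chosen K), \code{areas}, \code{delta_area}
#'   and \code{pac} (all named by K).
#' @export
select_k_delta_area <- function(result, threshold = 0.05,
                                pac_range = c(0.1, 0.9), pac_max = 0.1) {
  stopifnot(inherits(result, "ConsensusResult"), length(result$k_range) >= 2)
  ks <- result$k_range
  areas <- vapply(as.character(ks),
                  function(k) consensus_cdf_area(result$consensus[[k]])$area,
                  numeric(1))
  pac <- vapply(as.character(ks), function(k) {
    v <- result$consensus[[k]][upper.tri(result$consensus[[k]])]
    mean(v > pac_range[1] & v < pac_range[2])
  }, numeric(1))
  delta <- c(NA_real_, diff(areas) / areas[-length(areas)])
  names(delta) <- names(areas) <- names(pac) <- as.character(ks)
  passing <- ks[-1][!is.na(delta[-1]) & delta[-1] >= threshold &
                      pac[-1] <= pac_max]
  k <- if (length(passing) > 0) max(passing) else min(ks)
  list(k = k, areas = areas, delta_area = delta, pac = pac)
}

#' Seeded k-means with multiple restarts
#'
#' Lloyd-type k-means (via \code{stats::kmeans}) with \code{n_init} random
#' starts, keeping the solution with the lowest within-cluster sum of
#' squares.
#'
#' @param X numeric matrix, observations in rows.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_init number of random starts (default 10).
#' @return list with \code{labels}, \code{centers}, \code{tot_withinss}.
#' @export
kmeans_seeded <- function(X, k, seed = 0L, n_init = 10) {
  stopifnot(is.matrix(X))
  if (anyNA(X)) stop("k-means requires a complete matrix")
  if (k > nrow(X)) stop("k exceeds the number of observations")
  fit <- with_seed(seed, stats::kmeans(X, centers = k, nstart = n_init,
                                       iter.max = 100))
  list(labels = as.integer(fit$cluster), centers = fit$centers,
       tot_withinss = fit$tot.withinss)
}
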