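#' Benjamini-Hochberg adjustment with input validation
#'
#' Step-up false-discovery-rate adjustment (delegating to
#' \code{stats::p.adjust}), with an explicit domain check on the inputs.
#'
#' @param p numeric vector of p-values in [0, 1] (NAs propagate).
#' @return adjusted p-values, capped at 1, monotone in the usual step-up
#'   sense.
#' @export
bh_adjust <- function(p) {
  ok <- is.na(p) | (p >= 0 & p <= 1)
  if (!all(ok)) stop("p-values outside [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' One-tailed Fisher overrepresentation test
#'
#' Upper-tail hypergeometric test of the overlap k between a hit list of
#' size n and a gene set of size K inside a stated universe of size N:
#' p = P(X >= k). The gene set is intersected with the universe before
#' testing; hits must be a subset of the universe.
#'
#' @param hits character vector of selected features.
#' @param gene_set character vector of set members.
#' @param universe character vector defining the background.
#' @return list of class \code{ORARecord}: \code{overlap} k, \code{set_size}
#'   K (after universe intersection), \code{n_hits} n, \code{universe_size}
#'   N, \code{p}.
#' @export
fisher_ora <- function(hits, gene_set, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  hits <- unique(hits)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  set_in <- intersect(unique(gene_set), universe)
  K <- length(set_in)
  n <- length(hits)
  N <- length(universe)
  k <- length(intersect(hits, set_in))
  if (K == 0) {
    warning("gene set is disjoint from the universe; p = 1")
    p <- 1
  } else {
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  structure(list(overlap = k, set_size = K, n_hits = n,
                 universe_size = N, p = p),
            class = "ORARecord")
}

#' Run ORA over a gene-set collection
#'
#' @param hits selected features.
#' @param collection named list of gene sets.
#' @param universe background features.
#' @param min_size,max_size gene-set size bounds after universe
#'   intersection (defaults 1 and unbounded).
#' @return data.frame with one row per tested set, BH-adjusted.
#' @export
ora_collection <- function(hits, collection, universe,
                           min_size = 1, max_size = Inf) {
  rows <- lapply(names(collection), function(nm) {
    rec <- suppressWarnings(fisher_ora(hits, collection[[nm]], universe))
    data.frame(set = nm, overlap = rec$overlap, set_size = rec$set_size,
               n_hits = rec$n_hits, universe_size = rec$universe_size,
               p = rec$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$set_size >= min_size & out$set_size <= max_size, , drop = FALSE]
  out$adj_p <- bh_adjust(out$p)
  out[order(out$p), ]
}

#' Ranking metric for pre-ranked GSEA
#'
#' score = coefficient x (-log10 p). For multi-group contrasts with several
#' coefficients per feature, the mean coefficient is used. Zero p-values
#' are clamped to the smallest positive double with a warning.
#'
#' @param coefficients numeric vector, or a matrix (features x contrasts)
#'   whose row means are used.
#' @param p numeric vector of p-values in (0, 1].
#' @return named numeric ranking scores.
#' @export
rank_metric <- function(coefficients, p) {
  if (is.matrix(coefficients)) coefficients <- rowMeans(coefficients)
  stopifnot(length(coefficients) == length(p))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values outside [0, 1]")
  if (any(p == 0, na.rm = TRUE)) {
    warning("zero p-value(s) clamped to .Machine$double.xmin")
    p[p == 0] <- .Machine$double.xmin
  }
  out <- coefficients * (-log10(p))
  names(out) <- names(coefficients)
  out
}

# Weighted Kolmogorov-Smirnov running-sum enrichment score for one set:
# hit steps proportional to |score|^weight, miss steps 1/(N - n); the ES is
# the extreme of the running sum (largest absolute deviation, signed).
gsea_es <- function(scores_sorted, in_set, weight = 1) {
  N <- length(scores_sorted)
  n <- sum(in_set)
  if (n == 0 || n == N) return(NA_real_)
  w <- abs(scores_sorted)^weight
  hit_total <- sum(w[in_set])
  if (hit_total == 0) return(0)
  step <- ifelse(in_set, w / hit_total, -1 / (N - n))
  run <- cumsum(step)
  run[which.max(abs(run))]
}

#' Pre-ranked gene-set enrichment analysis
#'
#' Features are sorted by decreasing ranking score; each set's enrichment
#' score (ES) is the extreme of the weighted Kolmogorov-Smirnov running
#' sum. The null distribution is obtained by randomly re-drawing each set's
#' member labels (\code{n_perm} times, seeded); the permutation p-value
#' compares |ES| with same-signed null ES values and
#' NES = ES / mean |null ES of matching sign|. P-values are BH-adjusted
#' across sets.
#'
#' @param ranked_scores named numeric vector (unique feature names, finite).
#' @param collection named list of gene sets.
#' @param weight exponent on |score| for hit increments (default 1).
#' @param n_perm number of label permutations (default 1000).
#' @param seed integer seed.
#' @return data.frame with set, size (overlap with ranked features), ES,
#'   NES, p, adj_p and leading-edge members; sets with no overlap are
#'   reported with NA statistics.
#' @export
preranked_gsea <- function(ranked_scores, collection, weight = 1,
                           n_perm = 1000, seed = 0L) {
  stopifnot(!is.null(names(ranked_scores)), all(is.finite(ranked_scores)))
  if (anyDuplicated(names(ranked_scores))) stop("duplicate feature names")
  ord <- order(ranked_scores, decreasing = TRUE)
  s <- ranked_scores[ord]
  feats <- names(s)
  N <- length(s)
  rows <- vector("list", length(collection))
  with_seed(seed, {
    for (i in seq_along(collection)) {
      members <- intersect(collection[[i]], feats)
      n <- length(members)
      if (n < 1 || n >= N) {
        rows[[i]] <- data.frame(set = names(collection)[i], size = n,
                                es = NA_real_, nes = NA_real_, p = NA_real_,
                                leading_edge = NA_character_,
                                stringsAsFactors = FALSE)
        next
      }
      in_set <- feats %in% members
      es <- gsea_es(s, in_set, weight)
      null_es <- vapply(seq_len(n_perm), function(b) {
        idx <- sample.int(N, n)
        flag <- logical(N); flag[idx] <- TRUE
        gsea_es(s, flag, weight)
      }, numeric(1))
      same_sign <- null_es[sign(null_es) == sign(es)]
      p <- if (length(same_sign) == 0) 1 / (n_perm + 1) else
        (sum(abs(same_sign) >= abs(es)) + 1) / (length(same_sign) + 1)
      nes <- if (length(same_sign) == 0) NA_real_ else
        es / mean(abs(same_sign))
      # leading edge: members at or before the running-sum extreme
      w <- abs(s)^weight
      hit_total <- sum(w[in_set])
      step <- ifelse(in_set, w / hit_total, -1 / (N - n))
      run <- cumsum(step)
      peak <- which.max(abs(run))
      le <- if (es >= 0) feats[seq_len(peak)][in_set[seq_len(peak)]] else
        feats[peak:N][in_set[peak:N]]
      rows[[i]] <- data.frame(set = names(collection)[i], size = n,
                              es = es, nes = nes, p = p,
                              leading_edge = paste(le, collapse = ";"),
                              stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out[order(out$p), ]
}
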