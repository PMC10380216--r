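#' Per-ROI expected background from negative control probes
#'
#' Background = geometric mean of the ROI's negative-probe counts (floored
#' at 1), broadcast to every gene of that ROI.
#'
#' @param negative_counts negative probes x ROIs matrix.
#' @return named numeric vector of per-ROI background levels.
#' @export
estimate_background <- function(negative_counts) {
  stopifnot(is.matrix(negative_counts), nrow(negative_counts) >= 1)
  if (any(negative_counts < 0)) stop("negative-probe counts must be non-negative")
  x <- pmax(negative_counts, 1)
  apply(x, 2, geom_mean)
}

#' Constrained log-scale cell abundance fit for one ROI
#'
#' Estimates non-negative cell-type abundances beta minimizing
#' sum_g [log2(y_g + c) - log2((X beta)_g + b_g + c)]^2
#' by projected Gauss-Newton with backtracking line search: the log-normal
#' error model of count data, with an additive expected background b.
#'
#' @param y observed gene counts (length G).
#' @param X cell profile matrix, genes x cell types, non-negative.
#' @param b expected background per gene (scalar or length G).
#' @param pseudocount c added inside both logs (default 1).
#' @param tol convergence tolerance on the objective decrease (default 1e-8).
#' @param max_iter iteration cap (default 1000).
#' @return list with \code{beta} (named, >= 0), \code{objective},
#'   \code{iterations}, \code{converged}.
#' @export
fit_cell_abundance <- function(y, X, b, pseudocount = 1, tol = 1e-8,
                               max_iter = 1000) {
  stopifnot(is.matrix(X), length(y) == nrow(X), all(X >= 0), all(y >= 0))
  if (length(b) == 1) b <- rep(b, length(y))
  stopifnot(length(b) == length(y), all(b >= 0))
  K <- ncol(X)
  t_log <- log2(y + pseudocount)
  obj <- function(beta) {
    f <- log2(as.vector(X %*% beta) + b + pseudocount)
    sum((f - t_log)^2)
  }
  beta <- rep(mean(y) / max(colSums(X), 1), K)  # small positive start
  cur <- obj(beta)
  converged <- FALSE
  iter <- 0
  lambda <- 1e-8
  while (iter < max_iter) {
    iter <- iter + 1
    mu <- as.vector(X %*% beta) + b + pseudocount
    r <- log2(mu) - t_log
    J <- X / (mu * log(2))            # d log2(mu) / d beta
    H <- crossprod(J) + lambda * diag(K)
    g <- crossprod(J, r)
    d <- tryCatch(-solve(H, g), error = function(e) -g)
    step <- 1
    improved <- FALSE
    for (ls in 1:30) {
      cand <- pmax(beta + step * as.vector(d), 0)
      val <- obj(cand)
      if (val < cur - 1e-15) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }
    decrease <- cur - val
    beta <- cand
    cur <- val
    if (decrease < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("cell abundance fit did not converge within ", max_iter, " iterations")
  names(beta) <- colnames(X)
  list(beta = beta, objective = cur, iterations = iter, converged = converged)
}

#' Deconvolve cell-type abundances across all ROIs
#'
#' Applies \code{\link{fit_cell_abundance}} column-wise with a per-ROI
#' background (typically from \code{\link{estimate_background}}).
#'
#' @param values genes x ROIs count matrix (restricted to the genes of the
#'   profile matrix; rows are matched by name).
#' @param profile_matrix genes x cell types reference profiles.
#' @param background per-ROI background vector (or scalar).
#' @param ... passed to \code{\link{fit_cell_abundance}}.
#' @return list with \code{abundance} (ROIs x cell types, >= 0) and
#'   \code{fit_info} (objective/convergence per ROI).
#' @export
deconvolve_rois <- function(values, profile_matrix, background, ...) {
  genes <- intersect(rownames(profile_matrix), rownames(values))
  if (length(genes) < ncol(profile_matrix))
    stop("fewer shared genes than cell types")
  X <- profile_matrix[genes, , drop = FALSE]
  if (length(background) == 1) background <- rep(background, ncol(values))
  stopifnot(length(background) == ncol(values))
  res <- lapply(seq_len(ncol(values)), function(j)
    fit_cell_abundance(values[genes, j], X, background[j], ...))
  abundance <- t(vapply(res, `[[`, numeric(ncol(X)), "beta"))
  dimnames(abundance) <- list(colnames(values), colnames(X))
  info <- data.frame(roi_id = colnames(values),
                     objective = vapply(res, `[[`, numeric(1), "objective"),
                     converged = vapply(res, `[[`, logical(1), "converged"),
                     stringsAsFactors = FALSE)
  list(abundance = abundance, fit_info = info)
}

#' Co-localization of tumor microenvironment elements
#'
#' Clusters cell types (rows) by k-means on z-scored abundance profiles and
#' reports the pairwise Pearson correlation between cell-type profiles.
#' Constant cell-type rows are excluded from the correlation matrix and
#' recorded.
#'
#' @param abundance ROIs x cell types matrix (e.g. from
#'   \code{\link{deconvolve_rois}}).
#' @param k number of row clusters.
#' @param seed integer seed for k-means restarts.
#' @return list with \code{clusters} (named integer vector per cell type),
#'   \code{correlation} (cell type x cell type), \code{excluded}.
#' @export
tme_colocalization <- function(abundance, k, seed = 0L) {
  stopifnot(is.matrix(abundance), ncol(abundance) >= 2, nrow(abundance) >= 3)
  prof <- t(abundance)                      # cell types x ROIs
  sds <- apply(prof, 1, stats::sd)
  excluded <- rownames(prof)[sds == 0]
  keep <- sds > 0
  z <- (prof[keep, , drop = FALSE] - rowMeans(prof[keep, , drop = FALSE])) /
    sds[keep]
  km <- kmeans_seeded(z, k, seed = seed)
  clusters <- stats::setNames(km$labels, rownames(z))
  cormat <- stats::cor(t(prof[keep, , drop = FALSE]))
  list(clusters = clusters, correlation = cormat, excluded = excluded)
}
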