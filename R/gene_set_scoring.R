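#' Rank-based single-sample gene-set score (singscore)
#'
#' Features are ranked ascending by expression (ties receive average ranks).
#' With N measured features and n set members, the raw score is the mean
#' rank of the members; it is rescaled against its theoretical bounds
#' min_raw = (n + 1) / 2 and max_raw = (2N - n + 1) / 2 and centered, giving
#' a score in [-0.5, 0.5]: +0.5 when the members are the n top-expressed
#' features, -0.5 when they are the n bottom-expressed ones. Sets are
#' treated as directional, up-regulated collections.
#'
#' @param expression named numeric vector of one sample's expression values.
#' @param up_set character vector of member symbols.
#' @return the centered score (numeric scalar).
#' @export
singscore <- function(expression, up_set) {
  if (length(expression) < 2) stop("expression vector needs >= 2 features")
  if (is.null(names(expression))) stop("expression vector must be named")
  members <- intersect(up_set, names(expression))
  if (length(members) == 0) stop("gene set does not intersect measured features")
  r <- rank(expression, ties.method = "average")
  n <- length(members)
  N <- length(expression)
  raw <- mean(r[members])
  min_raw <- (n + 1) / 2
  max_raw <- (2 * N - n + 1) / 2
  (raw - min_raw) / (max_raw - min_raw) - 0.5
}

#' Score a gene-set collection across all ROIs
#'
#' Applies \code{\link{singscore}} per set and ROI after removing sets whose
#' overlap with the measured features is below \code{min_overlap} (default
#' 10, the conventional minimum for a stable rank score).
#'
#' @param matrix_ features x ROIs expression matrix (any monotone scale).
#' @param collection named list of character vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param min_overlap minimum measured-feature overlap per retained set.
#' @return list of class \code{SingscoreMatrix}: \code{scores} (sets x ROIs),
#'   \code{overlap} (named overlap sizes of retained sets),
#'   \code{dropped} (names of removed sets).
#' @export
score_collection <- function(matrix_, collection, min_overlap = 10) {
  stopifnot(is.matrix(matrix_), length(collection) > 0)
  feats <- rownames(matrix_)
  overlap <- vapply(collection, function(s) length(intersect(s, feats)), integer(1))
  keep <- overlap >= min_overlap
  if (!any(keep)) stop("all gene sets fall below the minimum overlap of ", min_overlap)
  kept <- collection[keep]
  scores <- matrix(NA_real_, length(kept), ncol(matrix_),
                   dimnames = list(names(kept), colnames(matrix_)))
  # rank once per ROI, then reuse for every set
  for (j in seq_len(ncol(matrix_))) {
    r <- rank(matrix_[, j], ties.method = "average")
    names(r) <- feats
    N <- length(r)
    for (i in seq_along(kept)) {
      members <- intersect(kept[[i]], feats)
      n <- length(members)
      raw <- mean(r[members])
      scores[i, j] <- (raw - (n + 1) / 2) / ((2 * N - n + 1) / 2 - (n + 1) / 2) - 0.5
    }
  }
  structure(list(scores = scores, overlap = overlap[keep],
                 dropped = names(collection)[!keep]),
            class = "SingscoreMatrix")
}

#' @export
print.SingscoreMatrix <- function(x, ...) {
  cat(sprintf("SingscoreMatrix: %d gene sets x %d ROIs (%d sets dropped for low overlap)\n",
              nrow(x$scores), ncol(x$scores), length(x$dropped)))
  invisible(x)
}
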