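#' Log2 transformation and median centering of protein intensities
#'
#' Aligns each ROI's median observed intensity to the grand median of all
#' observed values. A pure global shift would leave between-sample offsets
#' in place, so "centering around the global median" is implemented as
#' per-ROI alignment to the grand median; the pure global variant is
#' available with \code{per_roi = FALSE}. Missing cells are untouched.
#'
#' @param intensity_matrix proteins x ROIs matrix. Raw (linear) intensities
#'   are log2-transformed first when \code{log2_input = FALSE}.
#' @param log2_input set to \code{FALSE} when intensities are still linear.
#' @param per_roi align every ROI's median to the grand median (default);
#'   otherwise apply a single global shift.
#' @return the centered log2 matrix.
#' @export
log_median_center <- function(intensity_matrix, log2_input = TRUE, per_roi = TRUE) {
  stopifnot(is.matrix(intensity_matrix))
  m <- intensity_matrix
  if (!log2_input) {
    if (any(m[!is.na(m)] <= 0)) stop("raw intensities must be positive before log2")
    m <- log2(m)
  }
  n_obs <- colSums(!is.na(m))
  if (any(n_obs < 2))
    stop("ROI(s) with fewer than 2 observed values: ",
         paste(colnames(m)[n_obs < 2], collapse = ", "))
  grand <- stats::median(m, na.rm = TRUE)
  if (per_roi) {
    med <- apply(m, 2, stats::median, na.rm = TRUE)
    m <- sweep(m, 2, med - grand, `-`)
  }
  # in both modes the overall median ends at the grand median
  if (!per_roi) m <- m - (stats::median(m, na.rm = TRUE) - grand)
  m
}

#' Filter features by completeness across ROIs
#'
#' Keeps features observed (non-missing) in at least \code{min_fraction} of
#' the ROIs — the standard 80%-quantified rule of label-free proteomics.
#'
#' @param matrix_ proteins x ROIs matrix with NAs for missing values.
#' @param min_fraction minimum observed fraction in (0, 1] (default 0.8).
#' @return the row-filtered matrix.
#' @export
filter_completeness <- function(matrix_, min_fraction = 0.8) {
  stopifnot(is.matrix(matrix_), min_fraction > 0, min_fraction <= 1)
  frac <- rowMeans(!is.na(matrix_))
  matrix_[frac >= min_fraction, , drop = FALSE]
}

#' Impute missing values with low-abundance draws (MinProb-style)
#'
#' Models missingness as missing-not-at-random due to low abundance: each
#' missing cell in ROI s is drawn from
#' Normal(mean = q-quantile of ROI s's observed values,
#'        sd = tune_sigma x median over features of the per-feature observed SD).
#' Seeded and reproducible.
#'
#' @param matrix_ log2-scale proteins x ROIs matrix, already
#'   completeness-filtered.
#' @param q quantile defining the per-ROI imputation mean (default 0.01).
#' @param tune_sigma multiplier on the global sigma (default 1).
#' @param seed integer seed.
#' @return list with \code{imputed} (complete matrix) and \code{record}
#'   (class \code{ImputationRecord}: logical mask of imputed cells, per-ROI
#'   imputation means, the global sigma and the seed).
#' @export
impute_minprob <- function(matrix_, q = 0.01, tune_sigma = 1.0, seed = 0L) {
  stopifnot(is.matrix(matrix_))
  n_obs <- colSums(!is.na(matrix_))
  if (any(n_obs < 5))
    stop("ROI(s) with fewer than 5 observed values: ",
         paste(colnames(matrix_)[n_obs < 5], collapse = ", "))
  mask <- is.na(matrix_)
  feat_sd <- apply(matrix_, 1, stats::sd, na.rm = TRUE)
  sigma <- tune_sigma * stats::median(feat_sd, na.rm = TRUE)
  roi_mean <- apply(matrix_, 2, function(v) quantile7(v[!is.na(v)], q))
  out <- matrix_
  with_seed(seed, {
    for (s in seq_len(ncol(out))) {
      miss <- which(mask[, s])
      if (length(miss) > 0)
        out[miss, s] <- stats::rnorm(length(miss), mean = roi_mean[s], sd = sigma)
    }
  })
  record <- structure(list(mask = mask, roi_mean = roi_mean, sigma = sigma,
                           q = q, tune_sigma = tune_sigma, seed = seed),
                      class = "ImputationRecord")
  list(imputed = out, record = record)
}

#' Full proteomic preprocessing on an AnnotatedMatrix
#'
#' Median-centers log2 intensities, applies the completeness filter and
#' imputes the remaining missing values with low-abundance draws.
#'
#' @param protein_am AnnotatedMatrix of log2 intensities (NAs = missing).
#' @param min_fraction completeness threshold (default 0.8).
#' @param q,tune_sigma,seed imputation parameters, see
#'   \code{\link{impute_minprob}}.
#' @return list with \code{processed} (complete AnnotatedMatrix),
#'   \code{record} (ImputationRecord) and \code{n_before}/\code{n_after}
#'   feature counts around the completeness filter.
#' @export
preprocess_proteins <- function(protein_am, min_fraction = 0.8, q = 0.01,
                                tune_sigma = 1.0, seed = 0L) {
  m <- log_median_center(protein_am$values)
  n_before <- nrow(m)
  m <- filter_completeness(m, min_fraction)
  imp <- impute_minprob(m, q = q, tune_sigma = tune_sigma, seed = seed)
  fm <- protein_am$feature_meta
  fm <- fm[fm$feature_id %in% rownames(m), , drop = FALSE]
  am <- annotated_matrix(imp$imputed, protein_am$roi_meta, fm)
  list(processed = am, record = imp$record,
       n_before = n_before, n_after = nrow(m))
}
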