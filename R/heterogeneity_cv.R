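#' Per-case coefficient of variation within tumor ROIs
#'
#' CV = sample SD / mean of each feature across one case's tumor ROIs.
#' NAT ROIs are excluded first (so tumor-vs-NAT differences cannot drive
#' the screen); cases with fewer than 2 tumor ROIs contribute no CVs. The
#' default scale is linear — for log2 input use \code{scale = "linear"}
#' after exponentiating, or \code{scale = "log"} to compute the CV of the
#' log values directly.
#'
#' @param values features x ROIs matrix (linear-scale values for the
#'   default; log2 values are fine with \code{scale = "log"}).
#' @param roi_meta annotation table with \code{roi_id}, \code{case_id},
#'   \code{tissue}.
#' @param scale "linear" (default) or "log".
#' @return list of class \code{CVTable}: \code{cv} (features x cases),
#'   \code{n_tumor_rois} per case (eligible cases only).
#' @export
per_case_cv <- function(values, roi_meta, scale = c("linear", "log")) {
  scale <- match.arg(scale)
  meta <- roi_meta[match(colnames(values), roi_meta$roi_id), , drop = FALSE]
  tumor <- meta$tissue == "tumor"
  counts <- table(meta$case_id[tumor])
  eligible <- names(counts)[counts >= 2]
  if (length(eligible) == 0) stop("no case with >= 2 tumor ROIs")
  cv <- vapply(eligible, function(cs) {
    cols <- which(tumor & meta$case_id == cs)
    sub <- values[, cols, drop = FALSE]
    apply(sub, 1, function(v) {
      m <- mean(v)
      if (scale == "linear" && m <= 0) return(NA_real_)
      stats::sd(v) / m
    })
  }, numeric(nrow(values)))
  cv <- matrix(cv, nrow = nrow(values),
               dimnames = list(rownames(values), eligible))
  structure(list(cv = cv,
                 n_tumor_rois = stats::setNames(as.integer(counts[eligible]),
                                                eligible)),
            class = "CVTable")
}

#' Select stably or variably expressed features from a CV table
#'
#' Per case, features are ranked by CV and membership in the bottom
#' (stable) or top (variable) \code{quantile_frac} is computed against the
#' empirical quantile (linear interpolation; boundary ties included). A
#' feature is selected when its membership count reaches \code{min_cases};
#' mode "variable_all" requires the top quantile in every eligible case.
#'
#' @param cv_table a \code{CVTable}.
#' @param quantile_frac quantile width (default 0.2, i.e. bottom/top 20%).
#' @param min_cases minimum number of cases (default 4); ignored for
#'   "variable_all".
#' @param mode "stable", "variable" or "variable_all".
#' @return character vector of selected feature names.
#' @export
select_features <- function(cv_table, quantile_frac = 0.2, min_cases = 4,
                            mode = c("stable", "variable", "variable_all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(cv_table, "CVTable"))
  cv <- cv_table$cv
  n_cases <- ncol(cv)
  if (mode != "variable_all" && min_cases > n_cases)
    stop("min_cases = ", min_cases, " exceeds the ", n_cases, " eligible cases")
  member <- vapply(seq_len(n_cases), function(j) {
    v <- cv[, j]
    ok <- !is.na(v)
    res <- rep(FALSE, length(v))
    if (mode == "stable") {
      thr <- quantile7(v[ok], quantile_frac)
      res[ok] <- v[ok] <= thr
    } else {
      thr <- quantile7(v[ok], 1 - quantile_frac)
      res[ok] <- v[ok] >= thr
    }
    res
  }, logical(nrow(cv)))
  counts <- rowSums(member)
  need <- if (mode == "variable_all") n_cases else min_cases
  rownames(cv)[counts >= need]
}
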