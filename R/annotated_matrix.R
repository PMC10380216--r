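#' Feature-by-ROI matrix with annotations
#'
#' The central data container of the package: a numeric matrix with features
#' (genes, probes or proteins) in rows and regions of interest (ROIs) in
#' columns, together with a per-feature metadata table and a per-ROI
#' annotation table. Missing values are allowed (log2 proteomic intensities
#' are typically incomplete); a missing cell is \code{NA}, never 0.
#'
#' ROI annotations follow the two-table layout of digital spatial profiling
#' studies: \code{roi_id}, \code{case_id}, \code{roi_kind} ("tROI" or
#' "pROI"), \code{tissue} ("tumor" or "NAT"), \code{morphology},
#' \code{parent_proi} (for tROIs nested in a larger proteomic region),
#' ordinal \code{immune_score}/\code{mucin_score}/\code{stroma_score}
#' in 0..3, and continuous \code{til_pct}.
#'
#' @param values numeric matrix, features x ROIs, with dimnames.
#' @param roi_meta data.frame of per-ROI annotations keyed by \code{roi_id};
#'   must cover every column of \code{values}.
#' @param feature_meta optional data.frame of per-feature metadata keyed by
#'   \code{feature_id}; defaults to a table holding only the row names.
#' @return an object of class \code{AnnotatedMatrix} with elements
#'   \code{values}, \code{feature_meta}, \code{roi_meta}.
#' @export
annotated_matrix <- function(values, roi_meta, feature_meta = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have feature row names and ROI column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature ids in matrix rows")
  if (anyDuplicated(colnames(values)))
    stop("duplicate ROI ids in matrix columns")
  if (is.null(feature_meta)) {
    feature_meta <- data.frame(feature_id = rownames(values),
                               stringsAsFactors = FALSE)
  }
  if (!"feature_id" %in% names(feature_meta))
    stop("'feature_meta' must contain a 'feature_id' column")
  if (!"roi_id" %in% names(roi_meta))
    stop("'roi_meta' must contain a 'roi_id' column")
  if (anyDuplicated(roi_meta$roi_id))
    stop("duplicate ROI ids in 'roi_meta'")
  missing_rois <- setdiff(colnames(values), roi_meta$roi_id)
  if (length(missing_rois) > 0)
    stop("ROIs missing from 'roi_meta': ", paste(missing_rois, collapse = ", "))
  roi_meta <- roi_meta[match(colnames(values), roi_meta$roi_id), , drop = FALSE]
  rownames(roi_meta) <- NULL
  fm <- feature_meta[match(rownames(values), feature_meta$feature_id), , drop = FALSE]
  if (anyNA(fm$feature_id))
    stop("features missing from 'feature_meta'")
  rownames(fm) <- NULL
  validate_roi_meta(roi_meta)
  structure(list(values = values, feature_meta = fm, roi_meta = roi_meta),
            class = "AnnotatedMatrix")
}

# Structural checks on the ROI annotation table. Scores must lie in 0..3;
# a tROI's parent pROI, when present in the table, must belong to the same case.
validate_roi_meta <- function(roi_meta) {
  for (col in c("immune_score", "mucin_score", "stroma_score")) {
    if (col %in% names(roi_meta)) {
      v <- roi_meta[[col]]
      if (any(!is.na(v) & (v < 0 | v > 3)))
        stop(sprintf("'%s' values must lie in 0..3", col))
    }
  }
  if (all(c("parent_proi", "case_id") %in% names(roi_meta))) {
    has_parent <- !is.na(roi_meta$parent_proi) & roi_meta$parent_proi != ""
    idx <- match(roi_meta$parent_proi[has_parent], roi_meta$roi_id)
    known <- !is.na(idx)
    bad <- roi_meta$case_id[has_parent][known] != roi_meta$case_id[idx[known]]
    if (any(bad))
      stop("parent pROI assigned to a different case than its tROI: ",
           paste(roi_meta$roi_id[has_parent][known][bad], collapse = ", "))
  }
  invisible(roi_meta)
}

#' @export
print.AnnotatedMatrix <- function(x, ...) {
  v <- x$values
  cat(sprintf("AnnotatedMatrix: %d features x %d ROIs\n", nrow(v), ncol(v)))
  nmiss <- sum(is.na(v))
  if (nmiss > 0)
    cat(sprintf("  missing cells: %d (%.1f%%)\n", nmiss, 100 * nmiss / length(v)))
  if ("roi_kind" %in% names(x$roi_meta))
    cat("  ROI kinds:", paste(names(table(x$roi_meta$roi_kind)),
                              table(x$roi_meta$roi_kind), collapse = ", "), "\n")
  if ("tissue" %in% names(x$roi_meta))
    cat("  tissue:", paste(names(table(x$roi_meta$tissue)),
                           table(x$roi_meta$tissue), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.AnnotatedMatrix <- function(x) dim(x$values)

# Subset an AnnotatedMatrix by feature and/or ROI index/name vectors,
# keeping metadata aligned.
#' Subset an AnnotatedMatrix
#' @param x an \code{AnnotatedMatrix}.
#' @param features,rois index or name vectors; \code{NULL} keeps all.
#' @return a new \code{AnnotatedMatrix}.
#' @export
am_subset <- function(x, features = NULL, rois = NULL) {
  v <- x$values
  if (!is.null(features)) v <- v[features, , drop = FALSE]
  if (!is.null(rois)) v <- v[, rois, drop = FALSE]
  annotated_matrix(v, x$roi_meta, x$feature_meta)
}
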