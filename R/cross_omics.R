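#' Average tROI-level values within their parent pROIs
#'
#' Arithmetic mean across the child tROIs of each pROI. pROIs without
#' mapped children are absent from the output (a message records them);
#' children mapped to a pROI of a different case raise an error.
#'
#' @param values features x tROIs matrix.
#' @param roi_meta annotation table covering the tROIs (columns
#'   \code{roi_id}, \code{case_id}, \code{parent_proi}) and, when present,
#'   the pROIs (used for the case check).
#' @return features x pROIs matrix of tROI means.
#' @export
aggregate_troi_to_proi <- function(values, roi_meta) {
  stopifnot(is.matrix(values))
  meta <- roi_meta[match(colnames(values), roi_meta$roi_id), , drop = FALSE]
  if (anyNA(meta$roi_id)) stop("tROIs missing from the annotation table")
  has_parent <- !is.na(meta$parent_proi) & meta$parent_proi != ""
  pmeta <- roi_meta[roi_meta$roi_id %in% meta$parent_proi[has_parent], , drop = FALSE]
  if (nrow(pmeta) > 0) {
    par_case <- pmeta$case_id[match(meta$parent_proi[has_parent], pmeta$roi_id)]
    bad <- !is.na(par_case) & par_case != meta$case_id[has_parent]
    if (any(bad))
      stop("tROI(s) mapped to a pROI of a different case: ",
           paste(meta$roi_id[has_parent][bad], collapse = ", "))
  }
  parents <- unique(meta$parent_proi[has_parent])
  out <- vapply(parents, function(p) {
    rowMeans(values[, which(has_parent & meta$parent_proi == p), drop = FALSE])
  }, numeric(nrow(values)))
  out <- matrix(out, nrow = nrow(values),
                dimnames = list(rownames(values), parents))
  skipped <- setdiff(roi_meta$roi_id[roi_meta$roi_kind == "pROI"], parents)
  if (length(skipped) > 0)
    message("pROI(s) without mapped tROIs excluded: ",
            paste(skipped, collapse = ", "))
  out
}

#' Correlate two omic layers over matched pROIs
#'
#' Per shared identifier (gene symbol or gene-set name), computes the
#' Pearson correlation between the tROI-aggregated values and the pROI
#' values over matched pROI columns, with the usual two-sided t-test and BH
#' adjustment. Identifiers with zero variance in either layer are excluded
#' and recorded.
#'
#' @param troi_agg features x pROIs matrix (output of
#'   \code{\link{aggregate_troi_to_proi}}).
#' @param proi_values features x pROIs matrix of the other layer.
#' @return list with \code{records} (identifier, n, r, p, adj_p),
#'   \code{excluded} (zero-variance identifiers) and \code{summary}
#'   (mean and SD of r, number of significant positive/negative at
#'   adj p < 0.05).
#' @export
correlate_layers <- function(troi_agg, proi_values) {
  ids <- intersect(rownames(troi_agg), rownames(proi_values))
  if (length(ids) < 1) stop("no shared identifiers between the layers")
  prois <- intersect(colnames(troi_agg), colnames(proi_values))
  if (length(prois) < 3) stop("fewer than 3 matched pROIs")
  a <- troi_agg[ids, prois, drop = FALSE]
  b <- proi_values[ids, prois, drop = FALSE]
  excluded <- character(0)
  rows <- lapply(ids, function(id) {
    x <- a[id, ]; y <- b[id, ]
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      excluded <<- c(excluded, id)
      return(NULL)
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(identifier = id, n = sum(ok), r = unname(ct$estimate),
               p = ct$p.value, stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(records) || nrow(records) == 0) stop("no correlatable identifiers")
  records$adj_p <- bh_adjust(records$p)
  summary <- list(mean_r = mean(records$r), sd_r = stats::sd(records$r),
                  n = nrow(records),
                  n_sig_pos = sum(records$adj_p < 0.05 & records$r > 0),
                  n_sig_neg = sum(records$adj_p < 0.05 & records$r < 0))
  list(records = records, excluded = excluded, summary = summary)
}
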