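#' Flag outlying probes within each gene target
#'
#' Probe-level quality control for multi-probe count panels. A probe is
#' flagged when either
#' (a) its geometric mean across ROIs falls below \code{ratio_threshold}
#' times the geometric mean of all probes of its gene, or
#' (b) it is a Grubbs outlier (at \code{grubbs_alpha}) among its gene's
#' probes in at least \code{roi_fraction} of ROIs.
#' Counts are floored at 1 before any geometric statistic so zeros are
#' well-defined and positive counts are untouched. Genes with a single probe are never flagged (a warning is
#' raised, since no within-gene comparison is possible).
#'
#' @param probe_counts numeric matrix, probes x ROIs.
#' @param probe_gene character vector mapping each probe row to its gene.
#' @param ratio_threshold rule (a) threshold (default 0.1).
#' @param grubbs_alpha significance level of the Grubbs test (default 0.01).
#' @param roi_fraction fraction of ROIs in which a probe must be a Grubbs
#'   outlier before rule (b) fires (default 0.2).
#' @return data.frame with columns \code{probe_id}, \code{gene},
#'   \code{reason} ("low_ratio" or "grubbs"); zero rows when nothing is
#'   flagged.
#' @export
detect_outlier_probes <- function(probe_counts, probe_gene,
                                  ratio_threshold = 0.1,
                                  grubbs_alpha = 0.01,
                                  roi_fraction = 0.2) {
  stopifnot(is.matrix(probe_counts), length(probe_gene) == nrow(probe_counts))
  if (any(probe_counts < 0)) stop("probe counts must be non-negative")
  x <- pmax(probe_counts, 1)
  flags <- list()
  n_probes <- table(probe_gene)
  singles <- names(n_probes)[n_probes < 2]
  if (length(singles) > 0)
    warning(length(singles), " gene(s) with a single probe are never flagged")
  for (g in setdiff(unique(probe_gene), singles)) {
    rows <- which(probe_gene == g)
    sub <- x[rows, , drop = FALSE]
    probe_gm <- apply(sub, 1, geom_mean)
    gene_gm <- geom_mean(probe_gm)
    low <- probe_gm < ratio_threshold * gene_gm
    for (j in which(low))
      flags[[length(flags) + 1]] <- data.frame(
        probe_id = rownames(sub)[j], gene = g, reason = "low_ratio",
        stringsAsFactors = FALSE)
    # rule (b): per-ROI Grubbs test across the gene's probes (log scale)
    out_count <- integer(length(rows))
    for (r in seq_len(ncol(sub))) {
      v <- log(sub[, r])
      i <- grubbs_outlier(v, grubbs_alpha)
      if (!is.na(i)) out_count[i] <- out_count[i] + 1
    }
    hit <- out_count / ncol(sub) >= roi_fraction
    for (j in which(hit & !low))
      flags[[length(flags) + 1]] <- data.frame(
        probe_id = rownames(sub)[j], gene = g, reason = "grubbs",
        stringsAsFactors = FALSE)
  }
  if (length(flags) == 0)
    return(data.frame(probe_id = character(0), gene = character(0),
                      reason = character(0), stringsAsFactors = FALSE))
  do.call(rbind, flags)
}

# Index of the single most extreme value if it exceeds the two-sided Grubbs
# critical value at level alpha, else NA. Needs n >= 3.
grubbs_outlier <- function(v, alpha) {
  n <- length(v)
  if (n < 3) return(NA_integer_)
  s <- stats::sd(v)
  if (s == 0) return(NA_integer_)
  dev <- abs(v - mean(v))
  g <- max(dev) / s
  tcrit <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  gcrit <- ((n - 1) / sqrt(n)) * sqrt(tcrit^2 / (n - 2 + tcrit^2))
  if (g > gcrit) which.max(dev) else NA_integer_
}

#' Collapse probe-level counts to gene-level counts
#'
#' Gene count = geometric mean of the gene's unflagged probe counts in each
#' ROI, with counts floored at 1 first so zeros are well-defined.
#'
#' @param probe_counts numeric matrix, probes x ROIs.
#' @param probe_gene gene symbol per probe row.
#' @param flags output of \code{\link{detect_outlier_probes}} (or NULL).
#' @return numeric matrix, genes x ROIs.
#' @export
collapse_to_gene_counts <- function(probe_counts, probe_gene, flags = NULL) {
  keep <- rep(TRUE, nrow(probe_counts))
  if (!is.null(flags) && nrow(flags) > 0)
    keep <- !(rownames(probe_counts) %in% flags$probe_id)
  genes <- unique(probe_gene)
  dead <- vapply(genes, function(g) !any(keep[probe_gene == g]), logical(1))
  if (any(dead))
    stop("all probes flagged for gene(s): ", paste(genes[dead], collapse = ", "))
  out <- matrix(NA_real_, length(genes), ncol(probe_counts),
                dimnames = list(genes, colnames(probe_counts)))
  for (g in genes) {
    rows <- which(probe_gene == g & keep)
    sub <- pmax(probe_counts[rows, , drop = FALSE], 1)
    out[g, ] <- apply(sub, 2, geom_mean)
  }
  out
}

#' Per-ROI limit of quantitation from negative control probes
#'
#' LOQ = geometric mean of the ROI's negative-probe counts times the squared
#' geometric standard deviation, where the GSD is the exponential of the
#' population (divide-by-n) standard deviation of natural-log counts. Counts
#' are floored at 1 first so zeros are well-defined.
#'
#' @param negative_counts numeric matrix, negative probes x ROIs.
#' @return named numeric vector of LOQ values per ROI.
#' @export
compute_loq <- function(negative_counts) {
  stopifnot(is.matrix(negative_counts), nrow(negative_counts) >= 2)
  if (any(negative_counts < 0)) stop("negative-probe counts must be non-negative")
  x <- pmax(negative_counts, 1)
  apply(x, 2, function(v) geom_mean(v) * geom_sd(v, population = TRUE)^2)
}

#' Third-quartile (Q3) normalization of gene counts
#'
#' Each ROI's counts are multiplied by
#' factor = geometric mean of all ROI Q3 values / that ROI's Q3,
#' so that third quartiles are aligned on their dataset-wide geometric mean.
#' Q3 uses linear interpolation between order statistics (quantile type 7).
#' Negative probes must be excluded before calling.
#'
#' @param gene_counts numeric matrix, genes x ROIs (gene-level, no negatives).
#' @return list with \code{normalized} (matrix) and \code{report}
#'   (data.frame: roi_id, q3, factor).
#' @export
q3_normalize <- function(gene_counts) {
  stopifnot(is.matrix(gene_counts))
  q3 <- apply(gene_counts, 2, quantile7, probs = 0.75)
  if (any(q3 <= 0))
    stop("non-positive Q3 for ROI(s): ",
         paste(colnames(gene_counts)[q3 <= 0], collapse = ", "))
  target <- geom_mean(q3)
  factor <- target / q3
  normalized <- sweep(gene_counts, 2, factor, `*`)
  list(normalized = normalized,
       report = data.frame(roi_id = colnames(gene_counts), q3 = as.numeric(q3),
                           factor = as.numeric(factor), stringsAsFactors = FALSE))
}

#' Full transcript preprocessing on a probe-level AnnotatedMatrix
#'
#' Runs probe QC, collapses to gene counts, computes per-ROI LOQ from the
#' negative probes and applies Q3 normalization. LOQ is reported but not
#' used to filter genes unless \code{loq_filter = TRUE}, in which case genes
#' whose counts fall below the LOQ in more than half the ROIs are dropped.
#'
#' @param probe_am AnnotatedMatrix of probe counts with
#'   \code{feature_meta$symbol} and \code{feature_meta$is_negative}.
#' @param ratio_threshold,grubbs_alpha see \code{\link{detect_outlier_probes}}.
#' @param loq_filter drop genes mostly below LOQ (off by default).
#' @return list with \code{normalized} (AnnotatedMatrix, genes x tROIs),
#'   \code{report} (per-ROI q3/factor/loq), \code{flags} (probe QC table).
#' @export
preprocess_transcripts <- function(probe_am, ratio_threshold = 0.1,
                                   grubbs_alpha = 0.01, loq_filter = FALSE) {
  fm <- probe_am$feature_meta
  stopifnot(all(c("symbol", "is_negative") %in% names(fm)))
  neg <- probe_am$values[fm$is_negative, , drop = FALSE]
  probes <- probe_am$values[!fm$is_negative, , drop = FALSE]
  probe_gene <- fm$symbol[!fm$is_negative]
  flags <- detect_outlier_probes(probes, probe_gene,
                                 ratio_threshold = ratio_threshold,
                                 grubbs_alpha = grubbs_alpha)
  genes <- collapse_to_gene_counts(probes, probe_gene, flags)
  loq <- compute_loq(neg)
  norm <- q3_normalize(genes)
  if (loq_filter) {
    below <- sweep(norm$normalized, 2, loq, `<`)
    keep <- rowMeans(below) <= 0.5
    norm$normalized <- norm$normalized[keep, , drop = FALSE]
  }
  report <- norm$report
  report$loq <- as.numeric(loq[report$roi_id])
  am <- annotated_matrix(norm$normalized, probe_am$roi_meta,
                         data.frame(feature_id = rownames(norm$normalized),
                                    symbol = rownames(norm$normalized),
                                    stringsAsFactors = FALSE))
  list(normalized = am, report = report, flags = flags)
}
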