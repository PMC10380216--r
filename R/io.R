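#' Read a feature-by-ROI matrix from a delimited text file
#'
#' Matrices are stored features-in-rows with a header of ROI ids and the
#' feature id in the first column. Empty cells and the literal "NA" are read
#' as missing values (never as 0, since 0 is a valid log2 intensity).
#'
#' @param path file path; tab-separated by default.
#' @param sep field separator.
#' @param orientation "features_in_rows" (default) or "rois_in_rows"
#'   (the matrix is transposed after reading).
#' @return a numeric matrix with feature row names and ROI column names.
#' @export
read_matrix <- function(path, sep = "\t", orientation = c("features_in_rows", "rois_in_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix file must contain a header and at least one row: ", path)
  fields <- strsplit(lines, sep, fixed = TRUE)
  header <- fields[[1]]
  ncol_expect <- length(header)
  body <- fields[-1]
  nf <- lengths(body)
  # trailing empty cells are dropped by strsplit; pad, but reject longer rows
  if (any(nf > ncol_expect) || any(nf < 2))
    stop(sprintf("ragged row(s) in %s (expected %d fields): line %d",
                 path, ncol_expect, which(nf > ncol_expect | nf < 2)[1] + 1L))
  ids <- vapply(body, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate feature ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- t(vapply(body, function(f) {
    f <- c(f[-1], rep("", ncol_expect - length(f)))
    suppressWarnings(as.numeric(ifelse(f == "" | f == "NA", NA, f)))
  }, numeric(ncol_expect - 1L)))
  rownames(vals) <- ids
  colnames(vals) <- header[-1]
  if (anyDuplicated(colnames(vals)))
    stop("duplicate ROI ids in header of ", path)
  if (orientation == "rois_in_rows") vals <- t(vals)
  vals
}

#' Write a feature-by-ROI matrix to a delimited text file
#'
#' Missing values are written as empty cells; \code{read_matrix} round-trips
#' the result losslessly for finite values.
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param sep field separator.
#' @param id_col header name for the feature-id column.
#' @export
write_matrix <- function(m, path, sep = "\t", id_col = "feature_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  fmt <- function(x) ifelse(is.na(x), "", format(x, digits = 15, trim = TRUE, scientific = FALSE))
  lines <- c(paste(c(id_col, colnames(m)), collapse = sep),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rownames(m)[i], fmt(m[i, ])), collapse = sep), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' Standard tab-separated GMT: set name, description, then member symbols.
#' Duplicate members within a set are dropped with a warning; order of first
#' occurrence is preserved.
#'
#' @param path path to a GMT file.
#' @return a named list of character vectors of class \code{GeneSetCollection}.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop(sprintf("malformed GMT line %d in %s: fewer than 3 fields", i, path))
    members <- f[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0)
      stop(sprintf("malformed GMT line %d in %s: empty gene set", i, path))
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate members in set '%s'; deduplicated", f[1]))
      members <- unique(members)
    }
    nms[i] <- f[1]
    sets[[i]] <- members
  }
  if (anyDuplicated(nms)) stop("duplicate gene-set names in ", path)
  names(sets) <- nms
  structure(sets, class = "GeneSetCollection")
}

#' Write a gene-set collection to a GMT file
#' @param collection named list of character vectors.
#' @param path output path.
#' @param descriptions optional character vector of set descriptions.
#' @export
write_gmt <- function(collection, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(collection))
  lines <- vapply(seq_along(collection), function(i)
    paste(c(names(collection)[i], descriptions[i], collection[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read ROI annotations from CSV
#' @param path CSV keyed by \code{roi_id}.
#' @return a data.frame, validated for score ranges and parent-case agreement.
#' @export
read_roi_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"roi_id" %in% names(df)) stop("annotation table must contain 'roi_id'")
  if (anyDuplicated(df$roi_id)) stop("duplicate ROI ids in ", path)
  validate_roi_meta(df)
  df
}

# Write a JSON provenance record next to a stage's outputs: inputs,
# parameters, seed and session versions, so every run is reconstructable.
write_provenance <- function(path, stage, params, inputs = character(0)) {
  rec <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = as.list(inputs),
    parameters = params,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("roiomics"))
  )
  jsonlite::write_json(rec, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
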