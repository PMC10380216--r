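#' Patient-level mean expression over tumor ROIs
#'
#' Arithmetic mean of each feature over every patient's tumor ROIs; NAT
#' regions are excluded first. Patients without any tumor ROI are dropped
#' with a warning.
#'
#' @param values features x ROIs matrix.
#' @param roi_meta annotation table with \code{roi_id}, \code{case_id},
#'   \code{tissue}.
#' @return patients x features matrix.
#' @export
patient_mean_expression <- function(values, roi_meta) {
  meta <- roi_meta[match(colnames(values), roi_meta$roi_id), , drop = FALSE]
  tumor <- meta$tissue == "tumor"
  patients <- unique(meta$case_id)
  has_tumor <- patients[patients %in% meta$case_id[tumor]]
  dropped <- setdiff(patients, has_tumor)
  if (length(dropped) > 0)
    warning("patient(s) without tumor ROIs excluded: ",
            paste(dropped, collapse = ", "))
  out <- matrix(vapply(has_tumor, function(p)
    rowMeans(values[, tumor & meta$case_id == p, drop = FALSE]),
    numeric(nrow(values))), nrow = nrow(values))
  dimnames(out) <- list(rownames(values), has_tumor)
  t(out)
}

#' Stratified Cox proportional-hazards fit for one covariate
#'
#' Partial-likelihood fit (Efron tie handling, via
#' \code{survival::coxph}) of a single continuous covariate with a stratum
#' term that allows different baseline hazards per stratum (e.g. drug
#' received). Monotone-likelihood (perfect separation) fits are flagged
#' and their confidence bounds reported as unbounded.
#'
#' @param survival_table data.frame with \code{os_years}, \code{event}
#'   (0/1) and the stratum column.
#' @param covariate numeric vector aligned with the rows of
#'   \code{survival_table}.
#' @param strata_column name of the stratum column (NULL for none).
#' @param feature label stored in the record.
#' @return list of class \code{CoxRecord}: \code{hr}, \code{ci_low},
#'   \code{ci_high}, \code{p}, \code{log_hr}, \code{se},
#'   \code{n_patients}, \code{n_events}, \code{strata}, \code{separation}.
#' @export
cox_stratified <- function(survival_table, covariate, strata_column = "drug",
                           feature = "feature") {
  st <- survival_table
  stopifnot(all(c("os_years", "event") %in% names(st)),
            length(covariate) == nrow(st))
  if (sum(st$event) < 2) stop("fewer than 2 events")
  if (stats::sd(covariate) == 0) stop("constant covariate")
  df <- data.frame(time = st$os_years, event = st$event, x = covariate)
  if (!is.null(strata_column)) {
    df$stratum <- st[[strata_column]]
    fml <- survival::Surv(time, event) ~ x + survival::strata(stratum)
  } else {
    fml <- survival::Surv(time, event) ~ x
  }
  fit <- suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
  beta <- unname(stats::coef(fit)[1])
  se <- sqrt(stats::vcov(fit)[1, 1])
  separation <- !is.finite(beta) || !is.finite(se) || abs(beta) > 15 || se > 50
  ci <- beta + c(-1, 1) * stats::qnorm(0.975) * se
  structure(list(feature = feature,
                 hr = exp(beta), log_hr = beta, se = se,
                 ci_low = if (separation) 0 else exp(ci[1]),
                 ci_high = if (separation) Inf else exp(ci[2]),
                 p = 2 * stats::pnorm(-abs(beta / se)),
                 n_patients = nrow(df), n_events = sum(df$event),
                 strata = if (is.null(strata_column)) NA_character_ else strata_column,
                 separation = separation),
            class = "CoxRecord")
}

#' @export
print.CoxRecord <- function(x, ...) {
  cat(sprintf("Cox fit [%s]: HR = %.3f (95%% CI %.3f-%.3f), p = %.3g, %d patients / %d events%s\n",
              x$feature, x$hr, x$ci_low, x$ci_high, x$p, x$n_patients,
              x$n_events,
              if (x$separation) " [monotone likelihood]" else ""))
  invisible(x)
}

#' Feature-by-feature survival screen
#'
#' Runs \code{\link{cox_stratified}} for each feature of a patient-level
#' expression matrix against a survival table, with a small-sample warning
#' below 10 patients.
#'
#' @param patient_expr patients x features matrix (e.g. from
#'   \code{\link{patient_mean_expression}}).
#' @param survival_table data.frame with \code{patient_id},
#'   \code{os_years}, \code{event} and the stratum column.
#' @param strata_column stratum column name (default "drug").
#' @return data.frame of per-feature Cox records with BH-adjusted p.
#' @export
cox_screen <- function(patient_expr, survival_table, strata_column = "drug") {
  st <- survival_table[match(rownames(patient_expr), survival_table$patient_id), ,
                       drop = FALSE]
  if (anyNA(st$patient_id)) stop("patients missing from the survival table")
  if (nrow(st) < 10)
    warning("fewer than 10 patients; hazard ratios are unstable at this size")
  rows <- lapply(colnames(patient_expr), function(f) {
    rec <- tryCatch(cox_stratified(st, patient_expr[, f], strata_column, feature = f),
                    error = function(e) NULL)
    if (is.null(rec)) return(NULL)
    data.frame(feature = f, hr = rec$hr, log_hr = rec$log_hr,
               ci_low = rec$ci_low, ci_high = rec$ci_high, p = rec$p,
               n_patients = rec$n_patients, n_events = rec$n_events,
               separation = rec$separation, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (!is.null(out)) out$adj_p <- bh_adjust(out$p)
  out
}
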