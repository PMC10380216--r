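#' Fit a per-feature Gaussian linear mixed model with a patient random intercept
#'
#' y = b0 + b1 * covariate + u_patient + e, fitted by REML
#' (\code{lme4::lmer}); the returned p-value is a Wald test of b1 under the
#' normal approximation. When the random-effect fit is singular or fails,
#' the model falls back to ordinary least squares and the record is marked.
#'
#' @param y numeric response (log2 scale).
#' @param covariate numeric covariate, non-constant.
#' @param patient_ids grouping factor for the random intercept.
#' @return list with \code{coefficient}, \code{se}, \code{p},
#'   \code{fallback_ols} (logical).
#' @export
fit_lmm_feature <- function(y, covariate, patient_ids) {
  stopifnot(length(y) == length(covariate), length(y) == length(patient_ids))
  if (length(unique(patient_ids)) < 2) stop("need >= 2 patients")
  if (stats::sd(covariate) == 0) stop("covariate is constant")
  df <- data.frame(y = y, x = covariate, patient = factor(patient_ids))
  fallback <- FALSE
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(y ~ x + (1 | patient), data = df, REML = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit) && !lme4::isSingular(fit, tol = 1e-5)) {
    co <- summary(fit)$coefficients
  } else {
    fallback <- TRUE
    co <- summary(stats::lm(y ~ x, data = df))$coefficients
  }
  beta <- co["x", "Estimate"]
  se <- co["x", "Std. Error"]
  list(coefficient = unname(beta), se = unname(se),
       p = 2 * stats::pnorm(-abs(beta / se)), fallback_ols = fallback)
}

# Shared worker: fit the LMM for every feature of a matrix and assemble the
# DE table with BH adjustment. `log2_transform` applies log2(x + 1) for
# count matrices.
fit_de_table <- function(values, covariate, patient_ids, log2_transform = FALSE) {
  if (log2_transform) values <- log2(values + 1)
  records <- lapply(seq_len(nrow(values)), function(i) {
    f <- fit_lmm_feature(values[i, ], covariate, patient_ids)
    data.frame(feature = rownames(values)[i], coefficient = f$coefficient,
               se = f$se, p = f$p, fallback_ols = f$fallback_ols,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, records)
  out$adj_p <- bh_adjust(out$p)
  out$fc <- 2^out$coefficient
  out
}

#' Tumor-versus-NAT differential expression
#'
#' Patients lacking either tissue type are excluded before fitting (their
#' ROIs contribute no rows). Per feature, a linear mixed model with a tumor
#' indicator and a patient random intercept is fitted; a feature is
#' significant when |coefficient| >= log2(min_fc) and BH-adjusted p <
#' alpha.
#'
#' @param am AnnotatedMatrix (genes or proteins x ROIs) with
#'   \code{roi_meta$tissue} in \{"tumor", "NAT"\} and \code{roi_meta$case_id}.
#' @param log2_transform apply log2(x + 1) (use for count matrices).
#' @param min_fc minimum fold change (default 1.5).
#' @param alpha BH-adjusted significance level (default 0.05).
#' @return data.frame of DE records (coefficient is tumor minus NAT, log2).
#' @export
tumor_vs_nat <- function(am, log2_transform = FALSE, min_fc = 1.5, alpha = 0.05) {
  meta <- am$roi_meta
  has_both <- tapply(meta$tissue, meta$case_id,
                     function(t) all(c("tumor", "NAT") %in% t))
  qualifying <- names(has_both)[has_both]
  if (length(qualifying) < 2)
    stop("fewer than 2 patients with both tumor and NAT tissue")
  keep <- meta$case_id %in% qualifying
  values <- am$values[, keep, drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  out <- fit_de_table(values, as.numeric(meta$tissue == "tumor"),
                      meta$case_id, log2_transform)
  out$significant <- abs(out$coefficient) >= log2(min_fc) & out$adj_p < alpha
  out$direction <- ifelse(out$coefficient > 0, "up", "down")
  out$n_patients <- length(qualifying)
  out
}

#' Ordinal-score trend differential expression
#'
#' For an ordinal ROI score (immune, mucin or stroma, levels in 0..3), NAT
#' ROIs are dropped, then any level observed in a single ROI is dropped
#' (it cannot inform a trend). The score enters the mixed model as a
#' numeric covariate. A feature is significant when (i) the per-level group
#' means (log2) are strictly monotone in the declared direction, (ii) the
#' span between the extreme level means is at least log2(min_fc), and
#' (iii) the BH-adjusted model p-value is below alpha.
#'
#' @param am AnnotatedMatrix with the score in \code{roi_meta[[score_column]]}.
#' @param score_column name of the ordinal annotation column.
#' @param direction "up" (increasing with the score) or "down".
#' @param log2_transform apply log2(x + 1) first (for counts).
#' @param min_fc,alpha significance rule parameters.
#' @return data.frame of DE records with per-level group means attached.
#' @export
ordinal_trend_de <- function(am, score_column, direction = c("up", "down"),
                             log2_transform = FALSE, min_fc = 1.5, alpha = 0.05) {
  direction <- match.arg(direction)
  meta <- am$roi_meta
  keep <- meta$tissue != "NAT" & !is.na(meta[[score_column]])
  score <- meta[[score_column]][keep]
  tab <- table(score)
  singleton <- as.numeric(names(tab)[tab < 2])
  if (length(singleton) > 0) {
    drop2 <- score %in% singleton
    idx <- which(keep)
    keep[idx[drop2]] <- FALSE
    score <- score[!drop2]
  }
  levels_used <- sort(unique(score))
  if (length(levels_used) < 2)
    stop("only one ordinal level remains for '", score_column, "'")
  values <- am$values[, keep, drop = FALSE]
  if (log2_transform) values <- log2(values + 1)
  out <- fit_de_table(values, score, meta$case_id[keep], log2_transform = FALSE)
  means <- t(vapply(seq_len(nrow(values)), function(i)
    vapply(levels_used, function(l) mean(values[i, score == l]), numeric(1)),
    numeric(length(levels_used))))
  colnames(means) <- paste0("mean_level_", levels_used)
  mono <- apply(means, 1, function(m) {
    d <- diff(m)
    if (direction == "up") all(d > 0) else all(d < 0)
  })
  span <- abs(means[, ncol(means)] - means[, 1])
  out <- cbind(out, as.data.frame(means))
  out$monotone <- mono
  out$span <- span
  out$significant <- mono & span >= log2(min_fc) & out$adj_p < alpha
  out$direction <- direction
  out$levels_used <- paste(levels_used, collapse = ",")
  out
}

#' Continuous-covariate differential expression
#'
#' Mixed model with a continuous ROI covariate (e.g. TIL percentage);
#' significance requires only BH-adjusted p < alpha — no fold-change rule,
#' since a unit of a continuous covariate carries no natural fold change.
#'
#' @param am AnnotatedMatrix with the covariate in
#'   \code{roi_meta[[covariate_column]]}; ROIs with a missing covariate are
#'   dropped.
#' @param covariate_column name of the numeric annotation column.
#' @param log2_transform apply log2(x + 1) first (for counts).
#' @param alpha BH-adjusted significance level.
#' @return data.frame of DE records.
#' @export
continuous_covariate_de <- function(am, covariate_column, log2_transform = FALSE,
                                    alpha = 0.05) {
  meta <- am$roi_meta
  keep <- !is.na(meta[[covariate_column]]) & meta$tissue != "NAT"
  cov <- meta[[covariate_column]][keep]
  if (length(unique(cov)) < 3) stop("covariate needs >= 3 distinct values")
  out <- fit_de_table(am$values[, keep, drop = FALSE], cov,
                      meta$case_id[keep], log2_transform)
  out$significant <- out$adj_p < alpha
  out$direction <- ifelse(out$coefficient > 0, "up", "down")
  out
}
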