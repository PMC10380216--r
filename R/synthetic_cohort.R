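#' Configuration for the synthetic ROI cohort generator
#'
#' Defines the study design the generator emulates: a small cohort of
#' patients, each contributing a fixed number of small transcriptomic ROIs
#' (tROIs, probe-level negative-binomial counts with several probes per gene
#' plus negative control probes) nested under a handful of larger proteomic
#' ROIs (pROIs, log-normal log2 intensities with intensity-dependent
#' missingness). Ground-truth effects are planted so that every downstream
#' stage has a known answer: tumor-vs-NAT shifts, immune-score gradients,
#' TIL-percentage slopes, inflated within-tumor variance, cross-omic
#' correlated gene/protein pairs, cell-type mixtures driving a dedicated
#' block of deconvolution genes, and patient-level proportional hazards.
#'
#' @param n_patients number of patients (default 7).
#' @param trois_per_patient tROIs per patient (default 12).
#' @param prois_per_patient integer range (min, max) of pROIs per patient
#'   (default c(2, 6)).
#' @param n_genes gene targets on the transcript panel (excluding the
#'   deconvolution block).
#' @param probes_per_gene probes per gene target (default 5).
#' @param n_neg_probes negative control probes per ROI.
#' @param n_proteins protein groups on the proteomic layer.
#' @param shared_symbols number of symbols measured on both layers.
#' @param nb_dispersion negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2).
#' @param patient_sd standard deviation (log2) of the per-feature,
#'   per-patient random effects (each patient has a feature-specific
#'   expression profile); chosen > ROI noise so interpatient variance
#'   dominates and clustering is patient-driven.
#' @param roi_noise_sd log2 SD of per-gene, per-ROI biological noise.
#' @param depth_sd log2 SD of per-ROI sequencing-depth factors.
#' @param tumor_effect_log2fc planted tumor-vs-NAT shift (log2) for planted
#'   DE features; signs alternate.
#' @param immune_gradient_log2fc planted log2 shift per immune-score step
#'   (genes) and per 5 TIL percentage points (proteins).
#' @param n_planted_de,n_planted_immune,n_planted_variable,n_planted_correlated
#'   numbers of planted features per category (per layer where applicable).
#'   The TIL slope planted on proteins is \code{immune_gradient_log2fc} per
#'   5 TIL percentage points, sized so the slope is recoverable from the
#'   couple dozen pROIs a cohort provides.
#' @param variable_inflation within-tumor variance multiplier for planted
#'   variable features (default 8).
#' @param target_correlation target cross-omic Pearson correlation for
#'   planted gene/protein pairs.
#' @param corr_latent_sd SD of the shared per-pROI latent factor that induces
#'   the planted cross-omic correlation.
#' @param protein_noise_sd log2 SD of protein measurement noise.
#' @param mnar_logistic_midpoint,mnar_logistic_slope parameters of the
#'   logistic missingness model: an intensity x is missing with probability
#'   \code{plogis(-slope * (x - midpoint))}.
#' @param cell_types number of cell types in the planted mixtures.
#' @param n_decon_genes genes in the deconvolution marker block.
#' @param hazard_log_hr planted log hazard ratio per SD of the designated
#'   feature's patient-mean expression.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a validated list of class \code{CohortConfig}.
#' @export
cohort_config <- function(n_patients = 7,
                          trois_per_patient = 12,
                          prois_per_patient = c(2, 6),
                          n_genes = 300,
                          probes_per_gene = 5,
                          n_neg_probes = 20,
                          n_proteins = 300,
                          shared_symbols = 150,
                          nb_dispersion = 0.15,
                          patient_sd = 0.5,
                          roi_noise_sd = 0.25,
                          depth_sd = 0.2,
                          tumor_effect_log2fc = 1,
                          immune_gradient_log2fc = 0.5,
                          n_planted_de = 20,
                          n_planted_immune = 15,
                          n_planted_variable = 15,
                          n_planted_correlated = 20,
                          variable_inflation = 8,
                          target_correlation = 0.8,
                          corr_latent_sd = 1.2,
                          protein_noise_sd = 0.4,
                          mnar_logistic_midpoint = 22,
                          mnar_logistic_slope = 1.2,
                          cell_types = 6,
                          n_decon_genes = 100,
                          hazard_log_hr = 0.7,
                          seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "CohortConfig"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  counts <- c("n_patients", "trois_per_patient", "n_genes", "probes_per_gene",
              "n_neg_probes", "n_proteins", "shared_symbols", "cell_types",
              "n_decon_genes")
  for (f in counts)
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] < 1 ||
        cfg[[f]] != round(cfg[[f]]))
      config_error(f, "must be a positive integer")
  if (cfg$probes_per_gene < 1) config_error("probes_per_gene", "must be >= 1")
  if (length(cfg$prois_per_patient) != 2 || any(cfg$prois_per_patient < 1) ||
      cfg$prois_per_patient[1] > cfg$prois_per_patient[2])
    config_error("prois_per_patient", "must be an increasing positive range (min, max)")
  if (cfg$nb_dispersion <= 0) config_error("nb_dispersion", "must be > 0")
  if (cfg$shared_symbols > min(cfg$n_genes, cfg$n_proteins))
    config_error("shared_symbols", "cannot exceed n_genes or n_proteins")
  for (f in c("n_planted_de", "n_planted_immune", "n_planted_variable",
              "n_planted_correlated"))
    if (cfg[[f]] < 0) config_error(f, "must be >= 0")
  if (cfg$n_planted_correlated > cfg$shared_symbols)
    config_error("n_planted_correlated", "cannot exceed shared_symbols")
  if (cfg$n_planted_de + cfg$n_planted_immune + cfg$n_planted_variable >
      cfg$n_genes - cfg$shared_symbols)
    config_error("n_planted_de", paste("planted feature categories must fit in the",
                 "layer-specific (non-shared) feature block"))
  if (!is.finite(cfg$mnar_logistic_slope) || cfg$mnar_logistic_slope <= 0)
    config_error("mnar_logistic_slope", "must be a positive finite number")
  if (!is.finite(cfg$mnar_logistic_midpoint))
    config_error("mnar_logistic_midpoint", "must be finite")
  mid_p <- stats::plogis(0)
  if (!(mid_p > 0 && mid_p < 1)) config_error("mnar_logistic_slope", "degenerate")
  invisible(cfg)
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. All generator randomness flows through this.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Inject intensity-dependent (MNAR) missingness into a matrix
#'
#' Each entry is set missing independently with probability
#' \code{plogis(-slope * (x - midpoint))}: low-abundance values are lost
#' preferentially, emulating the missingness mechanism of label-free
#' proteomics.
#'
#' @param intensity_matrix numeric matrix on log2 scale.
#' @param midpoint intensity at which the missingness probability is 0.5.
#' @param slope positive steepness of the logistic curve.
#' @param seed integer seed; the same seed yields the same mask.
#' @return the matrix with selected entries replaced by \code{NA}.
#' @export
inject_mnar_missingness <- function(intensity_matrix, midpoint, slope, seed) {
  if (!is.finite(midpoint) || !is.finite(slope)) stop("non-finite missingness parameters")
  if (slope <= 0) stop("'slope' must be positive")
  with_seed(seed, {
    p_missing <- stats::plogis(-slope * (intensity_matrix - midpoint))
    mask <- matrix(stats::runif(length(intensity_matrix)) < p_missing,
                   nrow = nrow(intensity_matrix))
    out <- intensity_matrix
    out[mask] <- NA_real_
    out
  })
}

#' Find the missingness midpoint that yields a target overall missing fraction
#'
#' Bisection over the logistic midpoint so that the expected fraction of
#' missing cells matches \code{target} for a given slope.
#'
#' @param intensity_matrix complete log2 intensity matrix.
#' @param target desired overall missing fraction in (0, 1).
#' @param slope logistic slope.
#' @return the calibrated midpoint (numeric scalar).
#' @export
calibrate_mnar_midpoint <- function(intensity_matrix, target, slope) {
  stopifnot(target > 0, target < 1, slope > 0)
  x <- intensity_matrix[is.finite(intensity_matrix)]
  expected <- function(mid) mean(stats::plogis(-slope * (x - mid)))
  lo <- min(x) - 20 / slope
  hi <- max(x) + 20 / slope
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (expected(mid) < target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Generate a paired transcriptomic/proteomic synthetic cohort
#'
#' Produces probe-level counts, protein intensities, ROI annotations, a
#' patient survival table and a \code{TruthBundle} recording every planted
#' effect. See \code{\link{cohort_config}} for the generative model.
#'
#' @param config a \code{CohortConfig}.
#' @return a list of class \code{SyntheticCohort} with elements
#'   \code{probe_counts} (AnnotatedMatrix, probes x tROIs, negative probes
#'   flagged in \code{feature_meta$is_negative}), \code{protein_intensities}
#'   (AnnotatedMatrix, proteins x pROIs, with MNAR missingness applied),
#'   \code{roi_annotations} (data.frame over all ROIs), \code{survival}
#'   (patient-level table) and \code{truth} (the TruthBundle, including the
#'   complete pre-missingness protein matrix and the cell profile matrix).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  patients <- sprintf("Case%d", seq_len(cfg$n_patients))

  ## ---- ROI layout ----------------------------------------------------
  n_proi <- sample(seq(cfg$prois_per_patient[1], cfg$prois_per_patient[2]),
                   cfg$n_patients, replace = TRUE)
  roi_rows <- list()
  for (i in seq_len(cfg$n_patients)) {
    pids <- sprintf("%s_pROI%02d", patients[i], seq_len(n_proi[i]))
    # one NAT pROI when the patient has at least 3 pROIs
    p_tissue <- rep("tumor", n_proi[i])
    if (n_proi[i] >= 3) p_tissue[n_proi[i]] <- "NAT"
    morph_pool <- c("tubular", "papillary", "solid")
    p_morph <- ifelse(p_tissue == "NAT", "NAT", sample(morph_pool, 1))
    roi_rows[[length(roi_rows) + 1]] <- data.frame(
      roi_id = pids, case_id = patients[i], roi_kind = "pROI",
      tissue = p_tissue, morphology = p_morph,
      til_pct = ifelse(p_tissue == "tumor", round(stats::runif(n_proi[i], 5, 40), 1), NA),
      immune_score = NA_real_,
      mucin_score = ifelse(p_tissue == "tumor", sample(0:3, n_proi[i], replace = TRUE), NA),
      stroma_score = ifelse(p_tissue == "tumor", sample(1:3, n_proi[i], replace = TRUE), NA),
      parent_proi = NA_character_, stringsAsFactors = FALSE)

    tids <- sprintf("%s_tROI%02d", patients[i], seq_len(cfg$trois_per_patient))
    t_tissue <- rep("tumor", cfg$trois_per_patient)
    n_nat_t <- min(2, cfg$trois_per_patient - 1)
    t_tissue[seq_len(n_nat_t) + cfg$trois_per_patient - n_nat_t] <- "NAT"
    tumor_pids <- pids[p_tissue == "tumor"]
    nat_pid <- if (any(p_tissue == "NAT")) pids[p_tissue == "NAT"][1] else NA_character_
    parent <- character(cfg$trois_per_patient)
    parent[t_tissue == "tumor"] <-
      rep(tumor_pids, length.out = sum(t_tissue == "tumor"))
    parent[t_tissue == "NAT"] <- nat_pid
    # immune score: tumor tROIs cycle 1..3 so every patient shows all levels
    imm <- rep(NA_real_, cfg$trois_per_patient)
    imm[t_tissue == "tumor"] <- rep(1:3, length.out = sum(t_tissue == "tumor"))
    imm[t_tissue == "NAT"] <- 0
    roi_rows[[length(roi_rows) + 1]] <- data.frame(
      roi_id = tids, case_id = patients[i], roi_kind = "tROI",
      tissue = t_tissue,
      morphology = ifelse(t_tissue == "NAT", "NAT", p_morph[1]),
      til_pct = NA_real_, immune_score = imm,
      mucin_score = NA_real_, stroma_score = NA_real_,
      parent_proi = parent, stringsAsFactors = FALSE)
  }
  ann <- do.call(rbind, roi_rows)
  tann <- ann[ann$roi_kind == "tROI", ]
  pann <- ann[ann$roi_kind == "pROI", ]
  n_troi <- nrow(tann)
  n_proi_total <- nrow(pann)

  ## ---- feature bookkeeping -------------------------------------------
  gene_syms <- sprintf("G%04d", seq_len(cfg$n_genes))
  # shared symbols sit at the front of both layers
  prot_syms <- c(gene_syms[seq_len(cfg$shared_symbols)],
                 sprintf("P%04d", seq_len(cfg$n_proteins - cfg$shared_symbols)))
  decon_syms <- sprintf("D%03d", seq_len(cfg$n_decon_genes))

  nonshared_genes <- gene_syms[(cfg$shared_symbols + 1):cfg$n_genes]
  idx <- 0
  take <- function(n) { out <- nonshared_genes[idx + seq_len(n)]; idx <<- idx + n; out }
  planted_de_genes <- take(cfg$n_planted_de)
  planted_immune_genes <- take(cfg$n_planted_immune)
  planted_var_genes <- take(cfg$n_planted_variable)
  nonshared_prots <- prot_syms[(cfg$shared_symbols + 1):cfg$n_proteins]
  pidx <- 0
  ptake <- function(n) {
    n <- min(n, length(nonshared_prots) - pidx)
    out <- nonshared_prots[pidx + seq_len(n)]; pidx <<- pidx + n; out
  }
  planted_de_prots <- ptake(cfg$n_planted_de)
  planted_til_prots <- ptake(cfg$n_planted_immune)
  planted_var_prots <- ptake(cfg$n_planted_variable)
  corr_syms <- gene_syms[seq_len(cfg$n_planted_correlated)]
  hazard_feature <- gene_syms[cfg$shared_symbols]  # shared, never planted elsewhere

  de_sign <- rep(c(1, -1), length.out = cfg$n_planted_de)

  ## ---- transcript layer ----------------------------------------------
  gene_mu <- 10^stats::runif(cfg$n_genes, 1, 4)      # ~3 orders of magnitude
  names(gene_mu) <- gene_syms
  # per-gene, per-patient random effects: interpatient differences are
  # feature-specific profiles (a global per-patient shift would be removed
  # by Q3 normalization and carry no clustering signal)
  pat_eff_rna <- matrix(stats::rnorm(cfg$n_genes * cfg$n_patients, 0, cfg$patient_sd),
                        nrow = cfg$n_genes, dimnames = list(gene_syms, patients))
  depth <- 2^stats::rnorm(n_troi, 0, cfg$depth_sd)
  names(depth) <- tann$roi_id

  # shared per-pROI latent factor for planted correlated pairs; it is
  # orthogonalized against the within-patient tumor-vs-NAT contrast (each
  # patient's NAT pROI inherits the mean of their tumor-pROI latents) so the
  # planted correlation cannot confound the planted tumor effects — the
  # latent value stays shared between both omic layers, which is all the
  # cross-omic correlation needs
  latent <- matrix(stats::rnorm(cfg$n_planted_correlated * n_proi_total, 0,
                                cfg$corr_latent_sd),
                   nrow = cfg$n_planted_correlated,
                   dimnames = list(corr_syms, pann$roi_id))
  for (i in seq_len(cfg$n_patients)) {
    p_idx <- which(pann$case_id == patients[i])
    nat_idx <- p_idx[pann$tissue[p_idx] == "NAT"]
    tum_idx <- p_idx[pann$tissue[p_idx] == "tumor"]
    if (length(nat_idx) > 0 && length(tum_idx) > 0 &&
        cfg$n_planted_correlated > 0)
      latent[, nat_idx] <- rowMeans(latent[, tum_idx, drop = FALSE])
  }

  is_tumor_t <- tann$tissue == "tumor"
  log2_mean <- matrix(rep(log2(gene_mu), n_troi), nrow = cfg$n_genes,
                      dimnames = list(gene_syms, tann$roi_id))
  log2_mean <- log2_mean + pat_eff_rna[, tann$case_id]
  # planted tumor effects
  log2_mean[planted_de_genes, is_tumor_t] <-
    log2_mean[planted_de_genes, is_tumor_t] + de_sign * cfg$tumor_effect_log2fc
  # planted immune-score gradient (centered at score 2)
  imm_t <- tann$immune_score
  if (length(planted_immune_genes) > 0)
    log2_mean[planted_immune_genes, is_tumor_t] <-
      log2_mean[planted_immune_genes, is_tumor_t] +
      matrix(cfg$immune_gradient_log2fc * (imm_t[is_tumor_t] - 2),
             nrow = length(planted_immune_genes),
             ncol = sum(is_tumor_t), byrow = TRUE)
  # cross-omic latent, broadcast to child tROIs
  has_parent <- !is.na(tann$parent_proi)
  log2_mean[corr_syms, has_parent] <- log2_mean[corr_syms, has_parent] +
    latent[, tann$parent_proi[has_parent], drop = FALSE]
  # biological ROI noise; planted variable genes get inflated within-tumor noise
  noise_sd <- matrix(cfg$roi_noise_sd, cfg$n_genes, n_troi,
                     dimnames = dimnames(log2_mean))
  noise_sd[planted_var_genes, is_tumor_t] <-
    cfg$roi_noise_sd * sqrt(cfg$variable_inflation)
  log2_mean <- log2_mean + stats::rnorm(length(log2_mean)) * noise_sd

  ## deconvolution block: counts driven by planted cell mixtures
  profile_mat <- matrix(stats::runif(cfg$n_decon_genes * cfg$cell_types, 0.5, 2),
                        nrow = cfg$n_decon_genes,
                        dimnames = list(decon_syms,
                                        sprintf("celltype%d", seq_len(cfg$cell_types))))
  markers_per <- split(seq_len(cfg$n_decon_genes),
                       rep(seq_len(cfg$cell_types), length.out = cfg$n_decon_genes))
  for (k in seq_len(cfg$cell_types))
    profile_mat[markers_per[[k]], k] <- stats::runif(length(markers_per[[k]]), 50, 200)
  pat_mix <- t(vapply(seq_len(cfg$n_patients),
                      function(i) as.numeric(rdirichlet1(rep(2, cfg$cell_types))),
                      numeric(cfg$cell_types)))
  frac <- t(vapply(seq_len(n_troi), function(r) {
    as.numeric(rdirichlet1(30 * pat_mix[match(tann$case_id[r], patients), ] + 0.05))
  }, numeric(cfg$cell_types)))
  rownames(frac) <- tann$roi_id
  colnames(frac) <- colnames(profile_mat)
  bg_mean <- 3
  decon_mean <- profile_mat %*% t(frac) + bg_mean   # genes x tROIs

  ## probe-level expansion and NB sampling
  all_syms <- c(gene_syms, decon_syms)
  gene_mean <- rbind(2^log2_mean, decon_mean)       # linear-scale gene means
  gene_mean <- sweep(gene_mean, 2, depth, `*`)
  probe_rel <- matrix(2^stats::rnorm(length(all_syms) * cfg$probes_per_gene, 0, 0.15),
                      nrow = length(all_syms))
  probe_rel <- probe_rel / rowMeans(probe_rel)
  size <- 1 / cfg$nb_dispersion
  n_probes_total <- length(all_syms) * cfg$probes_per_gene
  probe_gene <- rep(all_syms, each = cfg$probes_per_gene)
  probe_ids <- paste0(probe_gene, "_p", rep(seq_len(cfg$probes_per_gene),
                                            times = length(all_syms)))
  probe_factor <- as.vector(t(probe_rel))  # gene-major, matches probe_gene order
  probe_mu <- gene_mean[probe_gene, , drop = FALSE] * probe_factor
  counts <- matrix(stats::rnbinom(length(probe_mu), mu = probe_mu, size = size),
                   nrow = n_probes_total,
                   dimnames = list(probe_ids, tann$roi_id))
  neg_ids <- sprintf("NegProbe%02d", seq_len(cfg$n_neg_probes))
  neg_counts <- matrix(stats::rnbinom(cfg$n_neg_probes * n_troi,
                                      mu = bg_mean * rep(depth, each = cfg$n_neg_probes),
                                      size = size),
                       nrow = cfg$n_neg_probes,
                       dimnames = list(neg_ids, tann$roi_id))
  probe_values <- rbind(counts, neg_counts)
  feature_meta <- data.frame(
    feature_id = rownames(probe_values),
    symbol = c(probe_gene, rep(NA_character_, cfg$n_neg_probes)),
    is_negative = c(rep(FALSE, n_probes_total), rep(TRUE, cfg$n_neg_probes)),
    stringsAsFactors = FALSE)
  probe_am <- annotated_matrix(probe_values + 0.0, tann, feature_meta)

  ## ---- protein layer --------------------------------------------------
  prot_base <- stats::runif(cfg$n_proteins, 20, 30)
  names(prot_base) <- prot_syms
  pat_eff_prot <- matrix(stats::rnorm(cfg$n_proteins * cfg$n_patients, 0,
                                      cfg$patient_sd),
                         nrow = cfg$n_proteins,
                         dimnames = list(prot_syms, patients))
  is_tumor_p <- pann$tissue == "tumor"
  prot_mean <- matrix(rep(prot_base, n_proi_total), nrow = cfg$n_proteins,
                      dimnames = list(prot_syms, pann$roi_id))
  prot_mean <- prot_mean + pat_eff_prot[, pann$case_id]
  prot_mean[planted_de_prots, is_tumor_p] <-
    prot_mean[planted_de_prots, is_tumor_p] +
    rep(c(1, -1), length.out = length(planted_de_prots)) * cfg$tumor_effect_log2fc
  til <- pann$til_pct
  til_ok <- is_tumor_p & !is.na(til)
  if (length(planted_til_prots) > 0)
    prot_mean[planted_til_prots, til_ok] <-
      prot_mean[planted_til_prots, til_ok] +
      matrix((cfg$immune_gradient_log2fc / 5) * (til[til_ok] - mean(til[til_ok])),
             nrow = length(planted_til_prots), ncol = sum(til_ok), byrow = TRUE)
  prot_mean[corr_syms, ] <- prot_mean[corr_syms, ] + latent
  pnoise_sd <- matrix(cfg$protein_noise_sd, cfg$n_proteins, n_proi_total)
  pnoise_sd[match(planted_var_prots, prot_syms), is_tumor_p] <-
    cfg$protein_noise_sd * sqrt(cfg$variable_inflation)
  prot_complete <- prot_mean + stats::rnorm(length(prot_mean)) * pnoise_sd

  prot_missing <- inject_mnar_missingness(
    prot_complete, cfg$mnar_logistic_midpoint, cfg$mnar_logistic_slope,
    seed = cfg$seed + 101L)
  prot_am <- annotated_matrix(
    prot_missing, pann,
    data.frame(feature_id = prot_syms, symbol = prot_syms,
               shared = prot_syms %in% gene_syms, stringsAsFactors = FALSE))

  ## ---- survival --------------------------------------------------------
  troi_log2 <- log2_mean  # log2 expected gene signal per tROI (pre-probe, pre-depth)
  pm <- tapply(seq_len(n_troi)[is_tumor_t], tann$case_id[is_tumor_t],
               function(ix) mean(troi_log2[hazard_feature, ix]))
  z <- as.numeric(scale(pm[patients]))
  drug <- rep(c("Crizotinib", "Alectinib"),
              c(ceiling(0.7 * cfg$n_patients),
                cfg$n_patients - ceiling(0.7 * cfg$n_patients)))
  surv <- simulate_survival_times(z, cfg$hazard_log_hr, drug)
  surv$patient_id <- patients

  truth <- list(
    planted_de_genes = data.frame(feature = planted_de_genes,
                                  true_log2fc = de_sign * cfg$tumor_effect_log2fc,
                                  stringsAsFactors = FALSE),
    planted_de_proteins = data.frame(
      feature = planted_de_prots,
      true_log2fc = rep(c(1, -1), length.out = length(planted_de_prots)) *
        cfg$tumor_effect_log2fc, stringsAsFactors = FALSE),
    planted_immune_genes = planted_immune_genes,
    planted_til_proteins = planted_til_prots,
    planted_variable_genes = data.frame(
      feature = planted_var_genes,
      variance_factor = rep(cfg$variable_inflation, length(planted_var_genes)),
      stringsAsFactors = FALSE),
    planted_variable_proteins = data.frame(
      feature = planted_var_prots,
      variance_factor = rep(cfg$variable_inflation, length(planted_var_prots)),
      stringsAsFactors = FALSE),
    planted_correlated_pairs = data.frame(
      symbol = corr_syms,
      target_r = rep(cfg$target_correlation, length(corr_syms)),
      stringsAsFactors = FALSE),
    true_cell_fractions = frac,
    profile_matrix = profile_mat,
    decon_background_mean = bg_mean,
    hazard_feature = hazard_feature,
    true_patient_log_hazards = stats::setNames(cfg$hazard_log_hr * z, patients),
    complete_protein = prot_complete
  )
  structure(list(probe_counts = probe_am,
                 protein_intensities = prot_am,
                 roi_annotations = ann,
                 survival = surv,
                 truth = truth,
                 config = cfg),
            class = "SyntheticCohort")
}

# single Dirichlet draw via gamma normalization
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Exponential survival times with patient log-hazards and independent
# exponential censoring plus an administrative cutoff at 15 years.
simulate_survival_times <- function(z, log_hr, stratum,
                                    baseline_rate = 1 / 8,
                                    censor_rate = 1 / 20,
                                    admin_censor = 15) {
  n <- length(z)
  t_event <- stats::rexp(n, rate = baseline_rate * exp(log_hr * z))
  t_cens <- pmin(stats::rexp(n, rate = censor_rate), admin_censor)
  data.frame(patient_id = NA_character_,
             os_years = round(pmin(t_event, t_cens), 3),
             event = as.integer(t_event <= t_cens),
             drug = stratum,
             covariate_z = z,
             stringsAsFactors = FALSE)
}

#' Simulate a patient-level survival cohort under the generator's hazard model
#'
#' Convenience front-end used for repeated-sampling checks of the Cox stage:
#' standard-normal patient covariates, exponential event times with log
#' hazard \code{log_hr * z}, independent censoring and a two-level stratum.
#'
#' @param n_patients number of patients.
#' @param log_hr true log hazard ratio per covariate SD.
#' @param seed integer seed.
#' @return a survival data.frame as in \code{\link{generate_cohort}}.
#' @export
simulate_survival_cohort <- function(n_patients, log_hr, seed) {
  with_seed(seed, {
    z <- stats::rnorm(n_patients)
    drug <- sample(c("Crizotinib", "Alectinib"), n_patients,
                   replace = TRUE, prob = c(0.7, 0.3))
    out <- simulate_survival_times(z, log_hr, drug)
    out$patient_id <- sprintf("P%04d", seq_len(n_patients))
    out
  })
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  cat(sprintf("SyntheticCohort: %d patients, %d tROIs, %d pROIs (seed %d)\n",
              x$config$n_patients,
              sum(x$roi_annotations$roi_kind == "tROI"),
              sum(x$roi_annotations$roi_kind == "pROI"),
              x$config$seed))
  invisible(x)
}
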