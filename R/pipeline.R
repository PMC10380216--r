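#' Default pipeline configuration
#'
#' Assembles the configuration consumed by \code{\link{run_stage}} /
#' \code{\link{run_pipeline}}: the synthetic cohort design plus the tuning
#' parameters of each stage. Any element can be overridden through the
#' \code{...} arguments or a YAML file (\code{\link{load_pipeline_config}}).
#'
#' @param ... named overrides of top-level elements.
#' @return a nested configuration list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 0L,
    cohort = list(),                       # overrides for cohort_config()
    preprocess = list(min_fraction = 0.8, q = 0.01, tune_sigma = 1.0),
    scoring = list(min_overlap = 10, n_sets = 25, set_size = c(10, 40)),
    cluster = list(k_range = 2:6, reps = 1000, p_item = 0.8, p_feature = 0.8),
    de = list(min_fc = 1.5, alpha = 0.05),
    enrich = list(n_perm = 1000, weight = 1),
    decon = list(pseudocount = 1),
    survival = list(strata_column = "drug")
  )
  overrides <- list(...)
  for (nm in names(overrides)) cfg[[nm]] <- utils::modifyList(
    if (is.list(cfg[[nm]]) && is.list(overrides[[nm]])) cfg[[nm]] else list(),
    if (is.list(overrides[[nm]])) overrides[[nm]] else stats::setNames(list(overrides[[nm]]), nm)
  )
  for (nm in names(overrides))
    if (!is.list(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  cfg
}

#' Load a pipeline configuration from YAML
#' @param path YAML file whose top-level keys override
#'   \code{\link{pipeline_config}} defaults.
#' @return a configuration list.
#' @export
load_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  utils::modifyList(cfg, user)
}

pipeline_stages <- c("simulate", "preprocess-rna", "preprocess-protein",
                     "score", "cluster", "de", "enrich", "integrate",
                     "heterogeneity", "deconvolve", "survival")

#' Run one pipeline stage
#'
#' Each stage reads its inputs from \code{outdir} (written by earlier
#' stages), writes its outputs there, and records a JSON provenance file
#' (inputs, parameters, seed, versions). Stage "all" chains every stage on
#' the synthetic cohort.
#'
#' @param stage one of "simulate", "preprocess-rna", "preprocess-protein",
#'   "score", "cluster", "de", "enrich", "integrate", "heterogeneity",
#'   "deconvolve", "survival", "all".
#' @param config configuration list (see \code{\link{pipeline_config}}).
#' @param outdir working directory for stage inputs/outputs.
#' @return invisibly, the stage's main result object.
#' @export
run_stage <- function(stage, config = pipeline_config(), outdir) {
  if (identical(stage, "all")) {
    res <- NULL
    for (s in pipeline_stages) res <- run_stage(s, config, outdir)
    return(invisible(res))
  }
  if (!stage %in% pipeline_stages)
    stop("unknown stage '", stage, "'; expected one of: ",
         paste(c(pipeline_stages, "all"), collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fn <- switch(stage,
               "simulate" = stage_simulate,
               "preprocess-rna" = stage_preprocess_rna,
               "preprocess-protein" = stage_preprocess_protein,
               "score" = stage_score,
               "cluster" = stage_cluster,
               "de" = stage_de,
               "enrich" = stage_enrich,
               "integrate" = stage_integrate,
               "heterogeneity" = stage_heterogeneity,
               "deconvolve" = stage_deconvolve,
               "survival" = stage_survival)
  invisible(fn(config, outdir))
}

#' Run the full pipeline ("all") on the synthetic cohort
#' @inheritParams run_stage
#' @return invisibly, the last stage's result.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir) {
  run_stage("all", config, outdir)
}

require_input <- function(outdir, file, producer) {
  p <- file.path(outdir, file)
  if (!file.exists(p))
    stop("missing required input '", file, "'; run the '", producer,
         "' stage first")
  p
}

op <- function(outdir, file) file.path(outdir, file)

stage_simulate <- function(config, outdir) {
  cc <- do.call(cohort_config, utils::modifyList(
    list(seed = config$seed), config$cohort))
  cohort <- generate_cohort(cc)
  write_matrix(cohort$probe_counts$values, op(outdir, "probe_counts.tsv"),
               id_col = "probe_id")
  utils::write.csv(cohort$probe_counts$feature_meta,
                   op(outdir, "probe_meta.csv"), row.names = FALSE)
  write_matrix(cohort$protein_intensities$values, op(outdir, "protein_log2.tsv"),
               id_col = "protein")
  utils::write.csv(cohort$roi_annotations, op(outdir, "roi_annotations.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$survival, op(outdir, "survival.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(cohort$truth$profile_matrix),
                   op(outdir, "cell_profiles.csv"), row.names = TRUE)
  truth_small <- cohort$truth[c("planted_de_genes", "planted_de_proteins",
                                "planted_immune_genes", "planted_til_proteins",
                                "planted_variable_genes",
                                "planted_variable_proteins",
                                "planted_correlated_pairs", "hazard_feature")]
  jsonlite::write_json(truth_small, op(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  write_provenance(op(outdir, "provenance_simulate.json"), "simulate",
                   list(seed = cc$seed, n_patients = cc$n_patients))
  cohort
}

read_cohort_files <- function(outdir) {
  ann <- read_roi_annotations(require_input(outdir, "roi_annotations.csv", "simulate"))
  list(annotations = ann)
}

stage_preprocess_rna <- function(config, outdir) {
  probes <- read_matrix(require_input(outdir, "probe_counts.tsv", "simulate"))
  meta <- utils::read.csv(require_input(outdir, "probe_meta.csv", "simulate"),
                          stringsAsFactors = FALSE)
  ann <- read_cohort_files(outdir)$annotations
  am <- annotated_matrix(probes, ann[ann$roi_kind == "tROI", ], meta)
  res <- preprocess_transcripts(am)
  write_matrix(res$normalized$values, op(outdir, "gene_counts_norm.tsv"),
               id_col = "gene")
  jsonlite::write_json(res$report, op(outdir, "rna_norm_report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  write_provenance(op(outdir, "provenance_preprocess_rna.json"),
                   "preprocess-rna", list(),
                   inputs = c("probe_counts.tsv", "probe_meta.csv"))
  res
}

stage_preprocess_protein <- function(config, outdir) {
  prot <- read_matrix(require_input(outdir, "protein_log2.tsv", "simulate"))
  ann <- read_cohort_files(outdir)$annotations
  am <- annotated_matrix(prot, ann[ann$roi_kind == "pROI", ])
  pp <- config$preprocess
  res <- preprocess_proteins(am, min_fraction = pp$min_fraction, q = pp$q,
                             tune_sigma = pp$tune_sigma, seed = config$seed)
  write_matrix(res$processed$values, op(outdir, "protein_processed.tsv"),
               id_col = "protein")
  jsonlite::write_json(list(n_before = res$n_before, n_after = res$n_after,
                            sigma = res$record$sigma,
                            n_imputed = sum(res$record$mask[
                              rownames(res$processed$values), ])),
                       op(outdir, "protein_imputation.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(op(outdir, "provenance_preprocess_protein.json"),
                   "preprocess-protein", pp, inputs = "protein_log2.tsv")
  res
}

# A reproducible synthetic gene-set collection over the measured symbols:
# random sets drawn from the union of both layers' features.
synthesize_collection <- function(symbols, n_sets, size_range, seed) {
  with_seed(seed + 17L, {
    sets <- lapply(seq_len(n_sets), function(i) {
      n <- sample(seq(size_range[1], min(size_range[2], length(symbols))), 1)
      sort(sample(symbols, n))
    })
    names(sets) <- sprintf("SET_%02d", seq_len(n_sets))
    sets
  })
}

stage_score <- function(config, outdir) {
  genes <- read_matrix(require_input(outdir, "gene_counts_norm.tsv", "preprocess-rna"))
  prot <- read_matrix(require_input(outdir, "protein_processed.tsv",
                                    "preprocess-protein"))
  sc <- config$scoring
  gmt_path <- op(outdir, "gene_sets.gmt")
  if (!file.exists(gmt_path)) {
    symbols <- union(rownames(genes), rownames(prot))
    collection <- synthesize_collection(symbols, sc$n_sets, sc$set_size,
                                        config$seed)
    write_gmt(collection, gmt_path)
  }
  collection <- read_gmt(gmt_path)
  rna_scores <- score_collection(log2(genes + 1), collection,
                                 min_overlap = sc$min_overlap)
  prot_scores <- score_collection(prot, collection,
                                  min_overlap = sc$min_overlap)
  write_matrix(rna_scores$scores, op(outdir, "singscores_rna.tsv"),
               id_col = "gene_set")
  write_matrix(prot_scores$scores, op(outdir, "singscores_protein.tsv"),
               id_col = "gene_set")
  write_provenance(op(outdir, "provenance_score.json"), "score", sc,
                   inputs = c("gene_counts_norm.tsv", "protein_processed.tsv",
                              "gene_sets.gmt"))
  list(rna = rna_scores, protein = prot_scores)
}

stage_cluster <- function(config, outdir) {
  genes <- read_matrix(require_input(outdir, "gene_counts_norm.tsv", "preprocess-rna"))
  prot <- read_matrix(require_input(outdir, "protein_processed.tsv",
                                    "preprocess-protein"))
  cl <- config$cluster
  res_rna <- consensus_cluster(log2(genes + 1), k_range = cl$k_range,
                               reps = cl$reps, p_item = cl$p_item,
                               p_feature = cl$p_feature, seed = config$seed)
  res_prot <- consensus_cluster(prot, k_range = cl$k_range, reps = cl$reps,
                                p_item = cl$p_item, p_feature = cl$p_feature,
                                seed = config$seed + 1L)
  k_rna <- select_k_delta_area(res_rna)
  k_prot <- select_k_delta_area(res_prot)
  lab <- data.frame(roi_id = c(res_rna$items, res_prot$items),
                    layer = c(rep("tROI", length(res_rna$items)),
                              rep("pROI", length(res_prot$items))),
                    cluster = c(res_rna$labels[[as.character(k_rna$k)]],
                                res_prot$labels[[as.character(k_prot$k)]]),
                    stringsAsFactors = FALSE)
  utils::write.csv(lab, op(outdir, "consensus_labels.csv"), row.names = FALSE)
  jsonlite::write_json(list(k_rna = k_rna$k, k_protein = k_prot$k,
                            areas_rna = k_rna$areas,
                            areas_protein = k_prot$areas),
                       op(outdir, "consensus_k.json"), auto_unbox = TRUE,
                       digits = NA)
  write_provenance(op(outdir, "provenance_cluster.json"), "cluster", cl,
                   inputs = c("gene_counts_norm.tsv", "protein_processed.tsv"))
  list(rna = res_rna, protein = res_prot, k_rna = k_rna$k, k_protein = k_prot$k)
}

stage_de <- function(config, outdir) {
  genes <- read_matrix(require_input(outdir, "gene_counts_norm.tsv", "preprocess-rna"))
  prot <- read_matrix(require_input(outdir, "protein_processed.tsv",
                                    "preprocess-protein"))
  ann <- read_cohort_files(outdir)$annotations
  de <- config$de
  am_rna <- annotated_matrix(genes, ann[ann$roi_kind == "tROI", ])
  am_prot <- annotated_matrix(prot, ann[ann$roi_kind == "pROI", ])
  out <- list(
    tumor_vs_nat_rna = tumor_vs_nat(am_rna, log2_transform = TRUE,
                                    min_fc = de$min_fc, alpha = de$alpha),
    tumor_vs_nat_protein = tumor_vs_nat(am_prot, min_fc = de$min_fc,
                                        alpha = de$alpha),
    immune_trend_rna = ordinal_trend_de(am_rna, "immune_score", "up",
                                        log2_transform = TRUE,
                                        min_fc = de$min_fc, alpha = de$alpha),
    til_protein = continuous_covariate_de(am_prot, "til_pct", alpha = de$alpha),
    mucin_trend_protein = ordinal_trend_de(am_prot, "mucin_score", "up",
                                           min_fc = de$min_fc, alpha = de$alpha),
    stroma_trend_protein = ordinal_trend_de(am_prot, "stroma_score", "up",
                                            min_fc = de$min_fc, alpha = de$alpha))
  for (nm in names(out))
    utils::write.csv(out[[nm]], op(outdir, paste0("de_", nm, ".csv")),
                     row.names = FALSE)
  write_provenance(op(outdir, "provenance_de.json"), "de", de,
                   inputs = c("gene_counts_norm.tsv", "protein_processed.tsv",
                              "roi_annotations.csv"))
  out
}

stage_enrich <- function(config, outdir) {
  de_path <- require_input(outdir, "de_tumor_vs_nat_rna.csv", "de")
  de_rna <- utils::read.csv(de_path, stringsAsFactors = FALSE)
  collection <- read_gmt(require_input(outdir, "gene_sets.gmt", "score"))
  en <- config$enrich
  scores <- rank_metric(stats::setNames(de_rna$coefficient, de_rna$feature),
                        de_rna$p)
  gsea <- preranked_gsea(scores, collection, weight = en$weight,
                         n_perm = en$n_perm, seed = config$seed)
  hits <- de_rna$feature[de_rna$significant]
  ora <- if (length(hits) > 0)
    ora_collection(hits, collection, universe = de_rna$feature) else NULL
  utils::write.csv(gsea, op(outdir, "gsea_tumor_vs_nat_rna.csv"),
                   row.names = FALSE)
  if (!is.null(ora))
    utils::write.csv(ora, op(outdir, "ora_tumor_vs_nat_rna.csv"),
                     row.names = FALSE)
  write_provenance(op(outdir, "provenance_enrich.json"), "enrich", en,
                   inputs = c("de_tumor_vs_nat_rna.csv", "gene_sets.gmt"))
  list(gsea = gsea, ora = ora)
}

stage_integrate <- function(config, outdir) {
  genes <- read_matrix(require_input(outdir, "gene_counts_norm.tsv", "preprocess-rna"))
  prot <- read_matrix(require_input(outdir, "protein_processed.tsv",
                                    "preprocess-protein"))
  ann <- read_cohort_files(outdir)$annotations
  agg <- aggregate_troi_to_proi(genes, ann)
  gene_level <- correlate_layers(agg, prot)
  utils::write.csv(gene_level$records, op(outdir, "crossomics_gene.csv"),
                   row.names = FALSE)
  set_level <- NULL
  if (file.exists(op(outdir, "singscores_rna.tsv"))) {
    ss_rna <- read_matrix(op(outdir, "singscores_rna.tsv"))
    ss_prot <- read_matrix(op(outdir, "singscores_protein.tsv"))
    agg_ss <- aggregate_troi_to_proi(ss_rna, ann)
    set_level <- correlate_layers(agg_ss, ss_prot)
    utils::write.csv(set_level$records, op(outdir, "crossomics_geneset.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(list(gene = gene_level$summary,
                            gene_set = set_level$summary),
                       op(outdir, "crossomics_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  write_provenance(op(outdir, "provenance_integrate.json"), "integrate",
                   list(), inputs = c("gene_counts_norm.tsv",
                                      "protein_processed.tsv"))
  list(gene = gene_level, gene_set = set_level)
}

stage_heterogeneity <- function(config, outdir) {
  genes <- read_matrix(require_input(outdir, "gene_counts_norm.tsv", "preprocess-rna"))
  prot <- read_matrix(require_input(outdir, "protein_processed.tsv",
                                    "preprocess-protein"))
  ann <- read_cohort_files(outdir)$annotations
  cv_rna <- per_case_cv(genes, ann, scale = "linear")
  cv_prot <- per_case_cv(2^prot, ann, scale = "linear")
  res <- list(
    stable_genes = select_features(cv_rna, mode = "stable"),
    variable_genes = select_features(cv_rna, mode = "variable"),
    variable_genes_all = select_features(cv_rna, mode = "variable_all"),
    stable_proteins = select_features(cv_prot, mode = "stable"),
    variable_proteins = select_features(cv_prot, mode = "variable"))
  write_matrix(cv_rna$cv, op(outdir, "cv_genes.tsv"), id_col = "gene")
  write_matrix(cv_prot$cv, op(outdir, "cv_proteins.tsv"), id_col = "protein")
  for (nm in names(res))
    writeLines(res[[nm]], op(outdir, paste0(nm, ".txt")))
  write_provenance(op(outdir, "provenance_heterogeneity.json"),
                   "heterogeneity", list(quantile_frac = 0.2, min_cases = 4),
                   inputs = c("gene_counts_norm.tsv", "protein_processed.tsv"))
  res
}

stage_deconvolve <- function(config, outdir) {
  genes <- read_matrix(require_input(outdir, "gene_counts_norm.tsv", "preprocess-rna"))
  probes <- read_matrix(require_input(outdir, "probe_counts.tsv", "simulate"))
  meta <- utils::read.csv(op(outdir, "probe_meta.csv"), stringsAsFactors = FALSE)
  prof <- as.matrix(utils::read.csv(require_input(outdir, "cell_profiles.csv",
                                                  "simulate"), row.names = 1))
  rna_report <- jsonlite::read_json(require_input(outdir, "rna_norm_report.json",
                                                  "preprocess-rna"),
                                    simplifyVector = TRUE)
  neg <- probes[meta$is_negative, , drop = FALSE]
  bg <- estimate_background(neg)
  # background on the same (Q3-normalized) scale as the gene counts
  factors <- stats::setNames(rna_report$factor, rna_report$roi_id)
  bg <- bg[colnames(genes)] * factors[colnames(genes)]
  dec <- deconvolve_rois(genes, prof, bg,
                         pseudocount = config$decon$pseudocount)
  coloc <- tme_colocalization(dec$abundance, k = min(3, ncol(dec$abundance)),
                              seed = config$seed)
  write_matrix(t(dec$abundance), op(outdir, "tme_abundance.tsv"),
               id_col = "cell_type")
  utils::write.csv(data.frame(cell_type = names(coloc$clusters),
                              cluster = coloc$clusters),
                   op(outdir, "tme_clusters.csv"), row.names = FALSE)
  write_provenance(op(outdir, "provenance_deconvolve.json"), "deconvolve",
                   config$decon,
                   inputs = c("gene_counts_norm.tsv", "cell_profiles.csv"))
  list(deconvolution = dec, colocalization = coloc)
}

stage_survival <- function(config, outdir) {
  genes <- read_matrix(require_input(outdir, "gene_counts_norm.tsv", "preprocess-rna"))
  ann <- read_cohort_files(outdir)$annotations
  surv <- utils::read.csv(require_input(outdir, "survival.csv", "simulate"),
                          stringsAsFactors = FALSE)
  truth <- jsonlite::read_json(op(outdir, "truth.json"), simplifyVector = TRUE)
  pm <- patient_mean_expression(log2(genes + 1), ann)
  feats <- unique(c(truth$hazard_feature,
                    utils::head(colnames(pm), 20)))
  feats <- feats[feats %in% colnames(pm)]
  screen <- cox_screen(pm[, feats, drop = FALSE], surv,
                       strata_column = config$survival$strata_column)
  utils::write.csv(screen, op(outdir, "cox_screen.csv"), row.names = FALSE)
  write_provenance(op(outdir, "provenance_survival.json"), "survival",
                   config$survival,
                   inputs = c("gene_counts_norm.tsv", "survival.csv"))
  screen
}
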