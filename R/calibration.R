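# End-to-end simulation studies: planted-effect recovery and null
# calibration of the full generator -> QC -> phenome -> burden-test chain.

#' One planted-effect recovery replicate
#'
#' Simulates a cohort with a planted additive burden effect on one gene
#' and PheCode, pushes it through genotype masking, sample and variant
#' QC, qualifying-set construction, ICD-to-PheCode case calling and
#' principal-component computation, then estimates the planted log odds
#' ratio with the Firth burden regression (age, sex, site and PCs as
#' covariates).
#'
#' @param n_samples cohort size.
#' @param log_or planted per-allele log odds ratio.
#' @param prevalence baseline prevalence of the target PheCode.
#' @param seed replicate seed.
#' @param gene,category where the effect is planted.
#' @param n_pcs number of principal components in the model.
#' @return list with `beta_hat`, `se`, `p`, `n_carriers`, `n_analyzed`.
#' @export
planted_recovery_replicate <- function(n_samples = 15000L,
                                       log_or = 1.5,
                                       prevalence = 0.10,
                                       seed = 1L,
                                       gene = "GENE03",
                                       category = "all_rare",
                                       n_pcs = 10L) {
  cfg <- cohort_config(
    n_samples = n_samples, n_genes = 5L, variants_per_gene = 30L,
    maf_law_spec = maf_law("loguniform", 1e-3, 8e-3),
    phecode_specs = data.frame(phecode = "296.2",
                               prevalence = prevalence, loading = 0.3),
    planted_effects = list(planted_effect(gene, "296.2", category,
                                          log_or)),
    n_sites = 5L, seed = seed)
  co <- simulate_cohort(cfg)
  qc <- .qc_chain(co, n_pcs = n_pcs)
  ph <- .phenome_chain(co, qc$samples)
  y <- ph[, "296.2"]
  vids <- qualifying_variants(qc$qsets, gene, category)
  if (!length(vids)) stop("planted gene lost all variants in QC")
  burden <- burden_score(qc$gt, vids)
  covX <- .covariate_matrix(qc$covariates)
  fit <- firth_fit(cbind(covX, burden = burden), y)
  list(beta_hat = unname(fit$coefficients["burden"]),
       se = sqrt(fit$vcov["burden", "burden"]),
       p = NA_real_,
       n_carriers = sum(burden >= 1),
       n_analyzed = length(y))
}

#' One all-null PheWAS replicate
#'
#' Simulates a cohort with no planted effects, runs the full pipeline
#' (QC, qualifying sets, case calling, curation, the burden grid and
#' multiplicity control) and reports how many cells reach study-wide
#' FDR significance — under the null this should almost always be zero.
#'
#' @param n_samples cohort size.
#' @param seed replicate seed.
#' @param min_cases curation floor (kept at the pipeline default; lower
#'   it for very small cohorts).
#' @return list with `n_study_wide`, `n_suggestive`, `n_tested`,
#'   `p_values` (the tested cells' Firth p-values).
#' @export
null_phewas_replicate <- function(n_samples = 2500L, seed = 1L,
                                  min_cases = 75L) {
  cfg <- cohort_config(
    n_samples = n_samples, n_genes = 6L, variants_per_gene = 20L,
    maf_law_spec = maf_law("loguniform", 1e-3, 9e-3),
    phecode_specs = data.frame(
      phecode = c("296.2", "318", "300.1", "296.1", "313.1", "317.1"),
      prevalence = c(0.17, 0.18, 0.10, 0.06, 0.08, 0.05),
      loading = c(0.6, 0.4, 0.5, 0.5, 0.3, 0.4)),
    n_sites = 3L, seed = seed)
  co <- simulate_cohort(cfg)
  qc <- .qc_chain(co, n_pcs = 5L)
  ph <- .phenome_chain(co, qc$samples)
  cur <- curate_phecodes(ph, min_cases = min_cases)
  ph <- ph[, cur$kept, drop = FALSE]
  res <- run_phewas(ph, qc$qsets, qc$gt, qc$covariates,
                    genes = sort(unique(co$variants$gene)))
  res <- adjust_multiplicity(res)
  list(n_study_wide = sum(res$study_wide, na.rm = TRUE),
       n_suggestive = sum(res$suggestive, na.rm = TRUE),
       n_tested = sum(res$tested),
       p_values = res$p_firth[res$tested & !is.na(res$p_firth)])
}

# masking -> sample QC -> variant QC -> PCA -> covariates, in memory
.qc_chain <- function(co, n_pcs = 10L, thresholds = qc_thresholds()) {
  gt <- mask_genotypes(co$gt, co$ad_ref, co$ad_alt, co$dp, co$gq,
                       thresholds)
  sq <- sample_qc(gt, co$variants, thresholds)
  gt <- gt[, sq$keep, drop = FALSE]
  vq <- variant_qc(gt, thresholds)
  gt <- gt[vq$keep, , drop = FALSE]
  qsets <- build_qualifying_sets(co$annotations,
                                 variant_ids = rownames(gt))
  pcs <- pca_genotypes(gt, k = n_pcs)$scores
  demo <- co$demographics[match(colnames(gt), co$demographics$sample_id), ]
  covariates <- cbind(demo[, c("age", "sex", "site")],
                      as.data.frame(pcs))
  rownames(covariates) <- colnames(gt)
  list(gt = gt, qsets = qsets, covariates = covariates,
       samples = colnames(gt))
}

# ICD events -> PheCode case matrix for the QC-passed samples
.phenome_chain <- function(co, samples) {
  mapped <- map_icd_to_phecode(co$icd_events, co$icd_map)
  call_case_status(mapped$events, samples)
}
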