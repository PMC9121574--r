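# Stage orchestration: each stage reads the previous stage's artifacts
# from the output directory, writes its own plus a manifest (input
# hashes, config snapshot, seed), and is individually re-runnable.

#' Pipeline configuration
#'
#' @param out_dir directory receiving all stage artifacts.
#' @param sim_config optional [cohort_config()] for the `simulate` stage.
#' @param cohort_dir directory holding cohort inputs (defaults to the
#'   `simulate` stage's output under `out_dir`).
#' @param thresholds QC thresholds, [qc_thresholds()] by default.
#' @param bed_path optional BED region mask.
#' @param region_polarity `"remove_inside"` or `"keep_inside"`.
#' @param min_cases PheCode curation floor.
#' @param n_pcs number of ancestry principal components used as
#'   covariates.
#' @param categories qualifying categories for the grid.
#' @param go_table optional data.frame (term, domain, gene) for the
#'   gene-set stage.
#' @param go_background background gene count for GO tests.
#' @param seed integer seed.
#' @return a named list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(out_dir,
                            sim_config = NULL,
                            cohort_dir = file.path(out_dir, "cohort"),
                            thresholds = qc_thresholds(),
                            bed_path = NULL,
                            region_polarity = "remove_inside",
                            min_cases = 75L,
                            n_pcs = 10L,
                            categories = qualifying_categories(),
                            go_table = NULL,
                            go_background = 20000L,
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

.artifact <- function(config, ...) file.path(config$out_dir, ...)

.require_artifact <- function(path, stage, produced_by) {
  if (!file.exists(path))
    stop("stage '", stage, "' requires missing artifact '", path,
         "' (produced by stage '", produced_by, "')")
  path
}

.write_manifest <- function(config, stage, inputs, outputs) {
  snap <- config[!vapply(config, is.function, logical(1))]
  snap$thresholds <- config$thresholds
  snap$sim_config <- NULL   # summarized below to keep the manifest small
  if (!is.null(config$sim_config))
    snap$sim_config_fields <- config$sim_config[
      c("n_samples", "n_genes", "seed")]
  man <- list(stage = stage,
              seed = config$seed,
              inputs = as.list(tools::md5sum(inputs[file.exists(inputs)])),
              outputs = as.list(tools::md5sum(outputs[file.exists(outputs)])),
              config = snap)
  jsonlite::write_json(man,
                       .artifact(config, paste0("manifest_", stage, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  invisible(man)
}

.wt <- function(x, path)
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)

.rt <- function(path, ...)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, check.names = FALSE, ...)

.write_gt <- function(gt, path) {
  df <- data.frame(variant_id = rownames(gt), gt, check.names = FALSE,
                   stringsAsFactors = FALSE)
  .wt(df, path)
}

.read_gt <- function(path) {
  df <- .rt(path, colClasses = NA)
  gt <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(gt) <- "integer"
  rownames(gt) <- df$variant_id
  gt
}

#' Run one pipeline stage
#'
#' Stages: `simulate` (generate and write a synthetic cohort), `qc`
#' (genotype masking, sample and variant QC, optional region mask, PCA),
#' `classify` (qualifying-variant sets), `phenome` (ICD to PheCode
#' mapping, case calling, curation), `phewas` (the primary burden grid
#' with multiplicity control), `interactions` (age and sex interaction
#' scans), `genesets` (all-gene aggregate and optional GO-driven sets),
#' `report` (suggestive associations sorted by p). Every stage writes a
#' manifest with input hashes, a config snapshot and the seed, so re-runs
#' are bit-identical.
#'
#' @param stage stage name.
#' @param config a [pipeline_config()].
#' @return the stage's main artifact (invisibly for writing stages).
#' @export
run_stage <- function(stage = c("simulate", "qc", "classify", "phenome",
                                "phewas", "interactions", "genesets",
                                "report"),
                      config) {
  stage <- match.arg(stage)
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)
  switch(stage,
         simulate = .stage_simulate(config),
         qc = .stage_qc(config),
         classify = .stage_classify(config),
         phenome = .stage_phenome(config),
         phewas = .stage_phewas(config),
         interactions = .stage_interactions(config),
         genesets = .stage_genesets(config),
         report = .stage_report(config))
}

#' Run a chain of pipeline stages in order
#'
#' @param stages character vector of stages, executed in the given order.
#' @param config a [pipeline_config()].
#' @return result of the last stage.
#' @export
run_pipeline <- function(stages = c("simulate", "qc", "classify",
                                    "phenome", "phewas"),
                         config) {
  out <- NULL
  for (s in stages) out <- run_stage(s, config)
  invisible(out)
}

.stage_simulate <- function(config) {
  if (is.null(config$sim_config))
    stop("stage 'simulate' requires config field 'sim_config'")
  cohort <- simulate_cohort(config$sim_config)
  paths <- write_cohort(cohort, config$cohort_dir)
  .write_manifest(config, "simulate", character(0), unname(paths))
  invisible(paths)
}

.stage_qc <- function(config) {
  vcf <- .require_artifact(file.path(config$cohort_dir, "cohort.vcf"),
                           "qc", "simulate")
  cohort <- read_cohort_vcf(vcf)
  t <- config$thresholds

  gt <- mask_genotypes(cohort$gt, cohort$ad_ref, cohort$ad_alt,
                       cohort$dp, cohort$gq, t)
  if (!is.null(config$bed_path)) {
    bed <- read_bed(config$bed_path)
    keep_r <- apply_region_mask(cohort$variants, bed,
                                polarity = config$region_polarity)
    gt <- gt[keep_r, , drop = FALSE]
    cohort$variants <- cohort$variants[keep_r, , drop = FALSE]
  }
  sq <- sample_qc(gt, cohort$variants, t)
  gt <- gt[, sq$keep, drop = FALSE]
  vq <- variant_qc(gt, t)
  gt <- gt[vq$keep, , drop = FALSE]
  variants <- cohort$variants[vq$keep, , drop = FALSE]

  pcs <- pca_genotypes(gt, k = config$n_pcs)$scores

  out <- c(gt = .artifact(config, "gt_qc.tsv"),
           variants = .artifact(config, "variants_qc.tsv"),
           samples = .artifact(config, "sample_metrics.tsv"),
           vmetrics = .artifact(config, "variant_metrics.tsv"),
           pcs = .artifact(config, "pcs.tsv"))
  .write_gt(gt, out["gt"])
  .wt(variants, out["variants"])
  .wt(sq$metrics, out["samples"])
  .wt(cbind(variant_id = cohort$variants$variant_id, vq$metrics),
      out["vmetrics"])
  .wt(data.frame(sample_id = rownames(pcs), pcs, check.names = FALSE),
      out["pcs"])
  .write_manifest(config, "qc", vcf, unname(out))
  invisible(out)
}

.stage_classify <- function(config) {
  ann_path <- .require_artifact(file.path(config$cohort_dir,
                                          "annotations.tsv"),
                                "classify", "simulate")
  var_path <- .require_artifact(.artifact(config, "variants_qc.tsv"),
                                "classify", "qc")
  ann <- .rt(ann_path, colClasses = "character")
  variants <- .rt(var_path)
  qsets <- build_qualifying_sets(ann, variant_ids = variants$variant_id)
  out <- .artifact(config, "qualifying_sets.tsv")
  .wt(qsets$sets, out)
  .write_manifest(config, "classify", c(ann_path, var_path), out)
  invisible(out)
}

.stage_phenome <- function(config) {
  ev_path <- .require_artifact(file.path(config$cohort_dir,
                                         "icd_events.tsv"),
                               "phenome", "simulate")
  map_path <- .require_artifact(file.path(config$cohort_dir,
                                          "icd_map.tsv"),
                                "phenome", "simulate")
  gt_path <- .require_artifact(.artifact(config, "gt_qc.tsv"),
                               "phenome", "qc")
  events <- .rt(ev_path, colClasses = c("character", "character",
                                        "integer", "character"))
  mapping <- .rt(map_path, colClasses = c("character", "integer",
                                          "character"))
  samples <- colnames(.read_gt(gt_path))
  mapped <- map_icd_to_phecode(events, mapping)
  phenome <- call_case_status(mapped$events, samples)
  curation <- curate_phecodes(phenome, min_cases = config$min_cases)
  out <- c(phenome = .artifact(config, "phenome.tsv"),
           curation = .artifact(config, "phecode_curation.tsv"))
  .wt(data.frame(sample_id = rownames(phenome), phenome,
                 check.names = FALSE), out["phenome"])
  .wt(curation, out["curation"])
  .write_manifest(config, "phenome", c(ev_path, map_path, gt_path),
                  unname(out))
  invisible(out)
}

.read_phewas_inputs <- function(config, stage) {
  gt <- .read_gt(.require_artifact(.artifact(config, "gt_qc.tsv"),
                                   stage, "qc"))
  qsets <- list(sets = .rt(.require_artifact(
    .artifact(config, "qualifying_sets.tsv"), stage, "classify"),
    colClasses = "character"))
  ph_df <- .rt(.require_artifact(.artifact(config, "phenome.tsv"),
                                 stage, "phenome"))
  phenome <- as.matrix(ph_df[, -1, drop = FALSE])
  rownames(phenome) <- ph_df$sample_id
  curation <- .rt(.require_artifact(
    .artifact(config, "phecode_curation.tsv"), stage, "phenome"))
  demo <- .rt(.require_artifact(file.path(config$cohort_dir,
                                          "demographics.tsv"),
                                stage, "simulate"))
  pcs_df <- .rt(.require_artifact(.artifact(config, "pcs.tsv"),
                                  stage, "qc"))
  samples <- colnames(gt)
  demo <- demo[match(samples, demo$sample_id), , drop = FALSE]
  pcs <- pcs_df[match(samples, pcs_df$sample_id), -1, drop = FALSE]
  covariates <- cbind(demo[, c("age", "sex", "site")], pcs)
  rownames(covariates) <- samples
  curated <- as.character(curation$phecode[curation$kept])
  phenome <- phenome[samples, colnames(phenome) %in% curated,
                     drop = FALSE]
  list(gt = gt, qsets = qsets, phenome = phenome, covariates = covariates,
       genes = sort(unique(qsets$sets$gene)))
}

.stage_phewas <- function(config) {
  inp <- .read_phewas_inputs(config, "phewas")
  res <- run_phewas(inp$phenome, inp$qsets, inp$gt, inp$covariates,
                    genes = inp$genes, categories = config$categories)
  res <- adjust_multiplicity(res)
  out <- .artifact(config, "phewas.tsv")
  .wt(res, out)
  .write_manifest(config, "phewas",
                  .artifact(config, c("gt_qc.tsv", "qualifying_sets.tsv",
                                      "phenome.tsv")), out)
  invisible(out)
}

.stage_interactions <- function(config) {
  inp <- .read_phewas_inputs(config, "interactions")
  out <- character(0)
  for (mod in c("age", "sex")) {
    res <- interaction_scan(inp$phenome, inp$qsets, inp$gt,
                            inp$covariates, modifier = mod,
                            genes = inp$genes,
                            categories = config$categories)
    p <- .artifact(config, paste0("interactions_", mod, ".tsv"))
    .wt(res, p)
    out <- c(out, p)
  }
  .write_manifest(config, "interactions",
                  .artifact(config, "phewas.tsv"), out)
  invisible(out)
}

.stage_genesets <- function(config) {
  inp <- .read_phewas_inputs(config, "genesets")
  res <- gene_set_burden(inp$phenome, inp$qsets, inp$gt, inp$covariates,
                         set_genes = inp$genes, set_id = "ALL_GENES",
                         categories = config$categories)
  if (!is.null(config$go_table)) {
    go <- go_overrepresentation(inp$genes, config$go_table,
                                config$go_background)
    for (i in seq_len(nrow(go$top_per_domain))) {
      members <- strsplit(go$top_per_domain$study_members[i], ",")[[1]]
      if (!length(members)) next
      res_d <- gene_set_burden(
        inp$phenome, inp$qsets, inp$gt, inp$covariates,
        set_genes = members,
        set_id = paste0("GO_top_", go$top_per_domain$domain[i]),
        categories = config$categories)
      res <- rbind(res, res_d)
    }
    .wt(go$terms, .artifact(config, "go_terms.tsv"))
  }
  out <- .artifact(config, "genesets.tsv")
  .wt(res, out)
  .write_manifest(config, "genesets", .artifact(config, "phewas.tsv"),
                  out)
  invisible(out)
}

.stage_report <- function(config) {
  res_path <- .require_artifact(.artifact(config, "phewas.tsv"),
                                "report", "phewas")
  res <- .rt(res_path)
  sug <- res[res$suggestive %in% TRUE, , drop = FALSE]
  sug <- sug[order(sug$p_firth), , drop = FALSE]
  out <- .artifact(config, "report.tsv")
  .wt(sug, out)
  .write_manifest(config, "report", res_path, out)
  sug
}
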