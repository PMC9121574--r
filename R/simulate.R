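# Synthetic cohort generator: rare-variant panel genotypes with raw
# call-level fields, consequence annotations with a 7-predictor consensus
# structure, demographics, and ICD diagnosis events with planted per-gene
# burden effects. Gives every downstream stage realistic work without any
# access to protected data.

#' Minor-allele-frequency law for the generator
#'
#' @param type `"loguniform"` (default) or `"fixed"`.
#' @param lo,hi bounds of the log-uniform law, both in (0, 0.01].
#' @param value the degenerate frequency for `type = "fixed"`.
#' @return a list describing the law.
#' @export
maf_law <- function(type = c("loguniform", "fixed"),
                    lo = 1e-4, hi = 0.01, value = 0.005) {
  type <- match.arg(type)
  if (type == "loguniform") {
    if (!(lo > 0 && hi <= 0.01 && lo < hi))
      stop("maf_law: bounds must satisfy 0 < lo < hi <= 0.01")
    list(type = type, lo = lo, hi = hi)
  } else {
    if (!(value > 0 && value <= 0.01))
      stop("maf_law: value must lie in (0, 0.01]")
    list(type = type, value = value)
  }
}

.draw_maf <- function(law, n) {
  f <- switch(law$type,
    loguniform = exp(stats::runif(n, log(law$lo), log(law$hi))),
    fixed = rep(law$value, n))
  pmin(f, 0.0099)
}

#' Default PheCode specifications for the generator
#'
#' Psychiatric PheCodes with baseline prevalences spanning the 0.3-18%
#' range typical of EHR cohorts, and positive loadings on one shared
#' latent comorbidity factor (the simplest mechanism producing the
#' positively-skewed pairwise correlation structure of real phenomes).
#' The rarest codes fall below the 75-case curation floor at the default
#' cohort size, exercising the curation filter.
#'
#' @return data.frame with `phecode`, `prevalence`, `loading`.
#' @export
default_phecode_specs <- function() {
  data.frame(
    phecode = c("296.2", "296.22", "318", "313.1", "313.3", "296.1",
                "316", "317.1", "306", "315.3", "303.4", "295.1",
                "301", "295.3"),
    prevalence = c(0.171, 0.152, 0.183, 0.076, 0.038, 0.026,
                   0.029, 0.022, 0.116, 0.008, 0.009, 0.003,
                   0.007, 0.006),
    loading = c(0.6, 0.6, 0.4, 0.3, 0.3, 0.5,
                0.5, 0.5, 0.4, 0.3, 0.4, 0.5,
                0.4, 0.5),
    stringsAsFactors = FALSE)
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions the pipeline targets: a
#' targeted panel of 58 genes carrying ~13,000 rare variants (MAF < 1%)
#' sequenced to a mean depth above 500x in ~15,000 individuals recruited
#' across 10 sites (54.5% women, ages 6-100), with psychiatric PheCodes
#' at EHR-realistic prevalences correlated through one shared latent
#' factor. Per-call AD/DP/GQ fields follow a shifted-Poisson depth law
#' with configurable contamination fractions of low-GQ and
#' aberrant-allelic-balance calls so the QC filters have non-trivial
#' work. One tenth of true cases emit only a single ICD instance,
#' exercising the two-date case rule's censoring.
#'
#' @param n_samples,n_genes,variants_per_gene cohort and panel dimensions
#'   (`variants_per_gene` may be a single count or one per gene).
#' @param maf_law_spec frequency law from [maf_law()], support in (0, 0.01].
#' @param class_mix named proportions over ptv/missense/synonymous/other;
#'   must sum to 1.
#' @param predictor_concordance probability each of the 7 deleteriousness
#'   predictors agrees with the variant's latent deleterious flag.
#' @param deleterious_fraction fraction of missense variants latently
#'   deleterious.
#' @param n_sites,sex_fraction,age_range demographic structure.
#' @param n_subpops,subpop_scale number of latent subpopulations and the
#'   log-scale SD of per-subpop allele-frequency perturbations.
#' @param phecode_specs data.frame from [default_phecode_specs()] or
#'   same-shaped.
#' @param planted_effects list of [planted_effect()] entries.
#' @param beta_age,beta_sex,site_sd covariate effects on the liability
#'   (per year of age centered at 50; for female sex; SD of site effects).
#' @param dp_mean,dp_shift depth law: `dp_shift + Poisson(dp_mean - dp_shift)`.
#' @param gq_low_fraction fraction of calls with contaminating GQ < 20.
#' @param ab_noise_fraction fraction of calls whose reads are drawn with a
#'   genotype-discordant allele fraction (gives the AB masks work).
#' @param single_code_fraction fraction of true cases emitting only one
#'   ICD instance.
#' @param seed integer seed governing all randomness.
#' @return validated config list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_samples = 15181L,
                          n_genes = 58L,
                          variants_per_gene = 224L,
                          maf_law_spec = maf_law(),
                          class_mix = c(ptv = 0.10, missense = 0.45,
                                        synonymous = 0.25, other = 0.20),
                          predictor_concordance = 0.9,
                          deleterious_fraction = 0.3,
                          n_sites = 10L,
                          sex_fraction = 0.545,
                          age_range = c(6, 100),
                          n_subpops = 1L,
                          subpop_scale = 0,
                          phecode_specs = default_phecode_specs(),
                          planted_effects = list(),
                          beta_age = 0.01,
                          beta_sex = 0.3,
                          site_sd = 0.15,
                          dp_mean = 500,
                          dp_shift = 10,
                          gq_low_fraction = 0.005,
                          ab_noise_fraction = 0.005,
                          single_code_fraction = 0.1,
                          seed = 1L) {
  cfg <- as.list(environment())
  .validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

.validate_config <- function(cfg) {
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid config field '", field, "': ", msg, call. = FALSE)
  chk(cfg$n_samples >= 2, "n_samples", "need at least 2 samples")
  chk(cfg$n_genes >= 1, "n_genes", "need at least 1 gene")
  chk(all(cfg$variants_per_gene >= 1), "variants_per_gene", "must be >= 1")
  chk(length(cfg$variants_per_gene) %in% c(1L, cfg$n_genes),
      "variants_per_gene", "length must be 1 or n_genes")
  chk(abs(sum(cfg$class_mix) - 1) < 1e-8 && all(cfg$class_mix >= 0),
      "class_mix", "proportions must be non-negative and sum to 1")
  chk(setequal(names(cfg$class_mix),
               c("ptv", "missense", "synonymous", "other")),
      "class_mix", "names must be ptv/missense/synonymous/other")
  chk(cfg$predictor_concordance >= 0 && cfg$predictor_concordance <= 1,
      "predictor_concordance", "must lie in [0,1]")
  chk(cfg$sex_fraction >= 0 && cfg$sex_fraction <= 1,
      "sex_fraction", "must lie in [0,1]")
  chk(cfg$n_subpops >= 1, "n_subpops", "must be >= 1")
  chk(all(cfg$phecode_specs$prevalence > 0 &
          cfg$phecode_specs$prevalence < 1),
      "phecode_specs", "prevalences must lie in (0,1)")
  chk(cfg$single_code_fraction >= 0 && cfg$single_code_fraction <= 1,
      "single_code_fraction", "must lie in [0,1]")
  for (pe in cfg$planted_effects)
    chk(pe$category %in% qualifying_categories(), "planted_effects",
        paste0("unknown category '", pe$category, "'"))
  invisible(TRUE)
}

#' A planted gene x PheCode burden effect
#'
#' @param gene gene identifier (as emitted by the generator, e.g. "GENE01").
#' @param phecode PheCode the effect acts on.
#' @param category qualifying-variant category carrying the effect.
#' @param log_or_per_allele effect size on the log-odds scale.
#' @param mode `"additive"` (per allele) or `"dominant"` (carrier).
#' @return list describing the effect.
#' @export
planted_effect <- function(gene, phecode, category = "all_rare",
                           log_or_per_allele = 0,
                           mode = c("additive", "dominant")) {
  mode <- match.arg(mode)
  if (!category %in% qualifying_categories())
    stop("invalid config field 'planted_effects': unknown category '",
         category, "'")
  list(gene = gene, phecode = as.character(phecode), category = category,
       log_or_per_allele = log_or_per_allele, mode = mode)
}

#' Simulate panel genotypes with raw call-level fields
#'
#' Draws per-variant frequencies from the configured law (optionally
#' perturbed per subpopulation on the log scale, truncated below 1%),
#' genotypes binomially, and populates AD/DP/GQ from the depth law with
#' the configured contamination fractions.
#'
#' @param config a [cohort_config()].
#' @param seed seed set before drawing (`NULL` to use the current RNG
#'   state, as [simulate_cohort()] does for downstream stages).
#' @return list with `gt` (variants x samples dosage matrix), `variants`
#'   (variant_id, chrom, pos, ref, alt, gene, maf_true), matrices
#'   `ad_ref`, `ad_alt`, `dp`, `gq`, and `subpop` per sample.
#' @export
simulate_genotypes <- function(config, seed = config$seed) {
  cfg <- config
  .validate_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n <- cfg$n_samples
  vpg <- rep(cfg$variants_per_gene, length.out = cfg$n_genes)
  m <- sum(vpg)
  genes <- sprintf("GENE%02d", seq_len(cfg$n_genes))
  gene_of <- rep(genes, vpg)
  chrom <- rep(sprintf("chr%d", (seq_len(cfg$n_genes) - 1L) %% 22L + 1L), vpg)
  pos <- unlist(lapply(seq_len(cfg$n_genes), function(g)
    sort(sample.int(50000L, vpg[g])) + g * 1000000L))

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
  # ~10% indels so the ins/del and Ts/Tv sample metrics are informative
  indel <- stats::runif(m) < 0.10
  ins <- indel & stats::runif(m) < 0.5
  alt[ins] <- paste0(ref[ins], sample(bases, sum(ins), replace = TRUE))
  del <- indel & !ins
  ref[del] <- paste0(ref[del], sample(bases, sum(del), replace = TRUE))
  alt[del] <- substr(ref[del], 1, 1)

  f <- .draw_maf(cfg$maf_law_spec, m)
  subpop <- sample.int(cfg$n_subpops, n, replace = TRUE)
  gt <- matrix(0L, m, n)
  for (s in seq_len(cfg$n_subpops)) {
    fs <- if (cfg$subpop_scale > 0)
      pmin(f * exp(stats::rnorm(m, 0, cfg$subpop_scale)), 0.0099) else f
    idx <- which(subpop == s)
    gt[, idx] <- stats::rbinom(m * length(idx), 2L, fs)
  }

  dp <- matrix(as.integer(cfg$dp_shift) +
                 stats::rpois(m * n, cfg$dp_mean - cfg$dp_shift), m, n)
  # genotype-conditional alt-read fraction, with a contaminating slice of
  # genotype-discordant fractions to exercise the AB masks
  efrac <- matrix(c(0.01, 0.5, 0.99)[gt + 1L], m, n)
  noisy <- stats::runif(m * n) < cfg$ab_noise_fraction
  efrac[noisy] <- stats::runif(sum(noisy), 0.05, 0.95)
  ad_alt <- matrix(stats::rbinom(m * n, as.vector(dp), as.vector(efrac)),
                   m, n)
  ad_ref <- dp - ad_alt
  gq <- matrix(99L, m, n)
  lowq <- stats::runif(m * n) < cfg$gq_low_fraction
  gq[lowq] <- sample(0:19, sum(lowq), replace = TRUE)

  vid <- sprintf("%s:%d:%s:%s", chrom, pos, ref, alt)
  sample_ids <- sprintf("S%05d", seq_len(n))
  dimnames(gt) <- list(vid, sample_ids)
  variants <- data.frame(variant_id = vid, chrom = chrom, pos = pos,
                         ref = ref, alt = alt, gene = gene_of,
                         maf_true = f, stringsAsFactors = FALSE)
  list(gt = gt, variants = variants, ad_ref = ad_ref, ad_alt = ad_alt,
       dp = dp, gq = gq, subpop = subpop)
}

.other_terms <- c("intron_variant", "5_prime_UTR_variant",
                  "3_prime_UTR_variant", "upstream_gene_variant")

#' Simulate consequence annotations and predictor calls
#'
#' Each variant draws one consequence term according to the configured
#' class mix, using the annotation vocabulary the classifier expects.
#' Missense variants carry a latent deleterious flag; each of the seven
#' predictors independently agrees with that flag with probability
#' `predictor_concordance` (`"D"` for deleterious, `"B"` for benign).
#'
#' @param variants variant table from [simulate_genotypes()].
#' @param config a [cohort_config()].
#' @return annotation data.frame: `variant_id`, `gene`,
#'   `consequence_term`, `pred1`..`pred7`, `latent_deleterious`.
#' @param seed seed set before drawing (`NULL` to continue the current
#'   RNG stream).
#' @export
simulate_annotations <- function(variants, config, seed = NULL) {
  cfg <- config
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(variants)
  cls <- sample(names(cfg$class_mix), m, replace = TRUE,
                prob = cfg$class_mix)
  term <- character(m)
  term[cls == "ptv"] <- sample(c("stop_gained", "frameshift_variant",
                                 "splice_acceptor_variant",
                                 "splice_donor_variant"),
                               sum(cls == "ptv"), replace = TRUE,
                               prob = c(0.4, 0.4, 0.1, 0.1))
  term[cls == "missense"] <- "missense_variant"
  term[cls == "synonymous"] <- "synonymous_variant"
  term[cls == "other"] <- sample(.other_terms, sum(cls == "other"),
                                 replace = TRUE)
  latent <- rep(NA, m)
  mis <- cls == "missense"
  latent[mis] <- stats::runif(sum(mis)) < cfg$deleterious_fraction
  preds <- matrix(NA_character_, m, 7,
                  dimnames = list(NULL, paste0("pred", 1:7)))
  if (any(mis)) {
    agree <- matrix(stats::runif(sum(mis) * 7) < cfg$predictor_concordance,
                    sum(mis), 7)
    truth <- matrix(ifelse(latent[mis], "D", "B"), sum(mis), 7)
    flipped <- matrix(ifelse(latent[mis], "B", "D"), sum(mis), 7)
    preds[mis, ] <- ifelse(agree, truth, flipped)
  }
  cbind(data.frame(variant_id = variants$variant_id, gene = variants$gene,
                   consequence_term = term, stringsAsFactors = FALSE),
        as.data.frame(preds, stringsAsFactors = FALSE),
        data.frame(latent_deleterious = latent))
}

#' Simulate demographics, latent liabilities and ICD diagnosis events
#'
#' Per sample and PheCode, the case probability is
#' `expit(intercept + age/sex/site effects + loading * shared factor +
#' planted burden effects)`, with the intercept calibrated numerically so
#' the marginal prevalence matches the spec. Cases emit two ICD codes
#' mapping to the PheCode on distinct calendar dates, except for a
#' configurable fraction emitting a single instance (which the two-date
#' case rule must censor); controls emit nothing for that code.
#'
#' @param genotypes result of [simulate_genotypes()].
#' @param qsets qualifying sets from [build_qualifying_sets()] (needed
#'   only when planted effects are configured).
#' @param config a [cohort_config()].
#' @param seed seed set before drawing (`NULL` to continue the current
#'   RNG stream).
#' @return list with `demographics`, `icd_events`, `icd_map`, and
#'   `truth` (samples x phecodes matrix of true case indicators).
#' @export
simulate_phenome <- function(genotypes, qsets = NULL, config, seed = NULL) {
  cfg <- config
  if (!is.null(seed)) set.seed(seed)
  n <- ncol(genotypes$gt)
  sample_ids <- colnames(genotypes$gt)
  age <- round(cfg$age_range[1] +
                 diff(cfg$age_range) * stats::rbeta(n, 2.2, 1.5))
  sex <- stats::rbinom(n, 1L, cfg$sex_fraction)        # 1 = female
  site <- sample.int(cfg$n_sites, n, replace = TRUE)
  site_eff <- stats::rnorm(cfg$n_sites, 0, cfg$site_sd)
  u <- stats::rnorm(n)                                  # shared factor

  planted_lp <- matrix(0, n, nrow(cfg$phecode_specs))
  colnames(planted_lp) <- cfg$phecode_specs$phecode
  for (pe in cfg$planted_effects) {
    if (!pe$gene %in% genotypes$variants$gene)
      stop("planted effect references absent gene '", pe$gene, "'")
    if (!pe$phecode %in% cfg$phecode_specs$phecode)
      stop("planted effect references absent phecode '", pe$phecode, "'")
    if (is.null(qsets))
      stop("planted effects require qualifying sets")
    vids <- qualifying_variants(qsets, pe$gene, pe$category)
    b <- burden_score(genotypes$gt, vids)
    if (pe$mode == "dominant") b <- as.numeric(b >= 1)
    planted_lp[, pe$phecode] <- planted_lp[, pe$phecode] +
      pe$log_or_per_allele * b
  }

  truth <- matrix(0L, n, nrow(cfg$phecode_specs),
                  dimnames = list(sample_ids, cfg$phecode_specs$phecode))
  for (j in seq_len(nrow(cfg$phecode_specs))) {
    spec <- cfg$phecode_specs[j, ]
    lp <- cfg$beta_age * (age - 50) + cfg$beta_sex * sex +
      site_eff[site] + spec$loading * u + planted_lp[, spec$phecode]
    intercept <- stats::uniroot(
      function(c0) mean(stats::plogis(c0 + lp)) - spec$prevalence,
      c(-25, 25), tol = 1e-8)$root
    truth[, j] <- stats::rbinom(n, 1L, stats::plogis(intercept + lp))
  }

  codes <- cfg$phecode_specs$phecode
  icd_map <- data.frame(
    icd_code = c(paste0("9-", codes), paste0("10-", codes)),
    icd_version = rep(c(9L, 10L), each = length(codes)),
    phecode = rep(codes, 2), stringsAsFactors = FALSE)

  dates <- seq(as.Date("2005-01-01"), as.Date("2020-12-31"), by = "day")
  ev <- vector("list", length(codes))
  for (j in seq_along(codes)) {
    cases <- which(truth[, j] == 1L)
    if (!length(cases)) next
    single <- stats::runif(length(cases)) < cfg$single_code_fraction
    # two-event cases get two distinct dates
    d1 <- sample(dates, length(cases), replace = TRUE)
    d2 <- pmin(d1 + sample(30:2000, length(cases), replace = TRUE),
               max(dates))
    d2[d2 == d1] <- d1[d2 == d1] - 1
    sid <- c(sample_ids[cases], sample_ids[cases][!single])
    date <- c(d1, d2[!single])
    version <- sample(c(9L, 10L), length(sid), replace = TRUE)
    ev[[j]] <- data.frame(
      sample_id = sid,
      icd_code = paste0(version, "-", codes[j]),
      icd_version = version,
      date = as.character(date), stringsAsFactors = FALSE)
  }
  icd_events <- do.call(rbind, ev)
  if (is.null(icd_events))
    icd_events <- data.frame(sample_id = character(),
                             icd_code = character(),
                             icd_version = integer(), date = character(),
                             stringsAsFactors = FALSE)
  list(
    demographics = data.frame(sample_id = sample_ids, age = age,
                              sex = sex, site = site,
                              stringsAsFactors = FALSE),
    icd_events = icd_events,
    icd_map = icd_map,
    truth = truth)
}

#' Simulate a complete cohort
#'
#' Runs genotype, annotation and phenome generation under one seed and
#' returns every artifact the pipeline consumes. Deterministic: the same
#' config (including its seed) reproduces the cohort exactly.
#'
#' @param config a [cohort_config()].
#' @return list with the genotype bundle (`gt`, `variants`, `ad_ref`,
#'   `ad_alt`, `dp`, `gq`, `subpop`), `annotations`, `qsets`,
#'   `demographics`, `icd_events`, `icd_map`, `truth`, and the `config`.
#' @export
simulate_cohort <- function(config) {
  cfg <- config
  .validate_config(cfg)
  g <- simulate_genotypes(cfg, seed = cfg$seed)
  ann <- simulate_annotations(g$variants, cfg, seed = cfg$seed + 1L)
  qsets <- build_qualifying_sets(ann)
  ph <- simulate_phenome(g, qsets, cfg, seed = cfg$seed + 2L)
  c(g, list(annotations = ann, qsets = qsets), ph, list(config = cfg))
}
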