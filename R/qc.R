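#' Default quality-control thresholds
#'
#' Returns the genotype-, sample- and variant-level QC thresholds used
#' throughout the pipeline. Genotypes are set to missing for homozygous
#' reference calls with allelic balance (AB) above `ab_homref_max`,
#' heterozygous calls with AB outside `[ab_het_min, ab_het_max]`,
#' homozygous alternate calls with AB below `ab_homalt_min`, and any call
#' with genotype quality below `gq_min` or depth below `dp_min`. Samples
#' are dropped at call rate below `sample_callrate_min` or when any of the
#' Ts/Tv, het/hom or ins/del ratios falls more than `ratio_outlier_sd`
#' standard deviations from the cohort mean. Variants are retained when
#' polymorphic, at call rate of at least `variant_callrate_min`, exact
#' Hardy-Weinberg p of at least `hwe_p_min`, and minor allele frequency
#' below `maf_max`. Ancestry labels require a posterior above
#' `ancestry_prob_min`.
#'
#' @param ... named overrides of any threshold.
#' @return named list of thresholds.
#' @export
qc_thresholds <- function(...) {
  t <- list(
    ab_homref_max = 0.1,
    ab_het_min = 0.25,
    ab_het_max = 0.75,
    ab_homalt_min = 0.9,
    gq_min = 20,
    dp_min = 10,
    sample_callrate_min = 0.975,
    ratio_outlier_sd = 3,
    variant_callrate_min = 0.95,
    hwe_p_min = 1e-6,
    maf_max = 0.01,
    ancestry_prob_min = 0.8
  )
  over <- list(...)
  bad <- setdiff(names(over), names(t))
  if (length(bad)) stop("unknown QC threshold(s): ", paste(bad, collapse = ", "))
  t[names(over)] <- over
  t
}

#' Genotype-level masking on allelic balance, GQ and DP
#'
#' Applies the per-call masking rules to a genotype matrix. A call is set
#' to missing when its allelic balance AB = alt reads / (ref + alt reads)
#' is inconsistent with the called genotype (hom-ref with AB > 0.1, het
#' with AB outside [0.25, 0.75], hom-alt with AB < 0.9), or when GQ < 20
#' or DP < 10. Calls with zero informative reads have undefined AB and are
#' set to missing (conservative, consistent with the depth filter).
#' The operation is idempotent and never restores a missing call.
#'
#' @param gt integer matrix (variants x samples) of alternate-allele counts
#'   0/1/2, `NA` for missing.
#' @param ad_ref,ad_alt,dp,gq numeric matrices of the same shape: reference
#'   and alternate read counts, depth, genotype quality.
#' @param thresholds list from [qc_thresholds()].
#' @return genotype matrix with failing calls set to `NA`.
#' @export
mask_genotypes <- function(gt, ad_ref, ad_alt, dp, gq,
                           thresholds = qc_thresholds()) {
  t <- thresholds
  inf_reads <- ad_ref + ad_alt
  ab <- ifelse(inf_reads > 0, ad_alt / inf_reads, NA_real_)
  fail <- (is.na(ab)) |
    (gt == 0L & ab > t$ab_homref_max) |
    (gt == 1L & (ab < t$ab_het_min | ab > t$ab_het_max)) |
    (gt == 2L & ab < t$ab_homalt_min) |
    (gq < t$gq_min) | (dp < t$dp_min)
  gt[which(fail)] <- NA_integer_
  gt
}

#' Split multiallelic records and trim to minimal representation
#'
#' Produces one biallelic record per alternate allele, trimming the shared
#' suffix then the shared prefix (always retaining at least one base) and
#' adjusting the position for each trimmed prefix base. Alternate alleles
#' identical to the reference after trimming are non-variants: they are
#' dropped with a warning, and an error is raised if no valid alternate
#' remains. Idempotent on already-minimal records.
#'
#' @param chrom chromosome.
#' @param pos 1-based position.
#' @param ref reference allele string.
#' @param alt character vector of alternate alleles (a multiallelic site).
#' @return data.frame with columns chrom, pos, ref, alt, one row per
#'   retained alternate allele.
#' @export
split_and_left_trim <- function(chrom, pos, ref, alt) {
  stopifnot(nzchar(ref), all(nzchar(alt)))
  rows <- lapply(alt, function(a) {
    r <- ref
    p <- pos
    # suffix trim
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    # prefix trim
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      p <- p + 1
    }
    if (r == a) return(NULL)
    data.frame(chrom = chrom, pos = p, ref = r, alt = a,
               stringsAsFactors = FALSE)
  })
  dropped <- vapply(rows, is.null, logical(1))
  if (all(dropped))
    stop("non-variant record: every alternate allele equals the reference")
  if (any(dropped))
    warning(sum(dropped), " alternate allele(s) identical to reference; dropped")
  do.call(rbind, rows[!dropped])
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test conditioning on the observed allele counts:
#' enumerates every heterozygote count compatible with the allele counts,
#' computes its conditional probability, and sums the probabilities of
#' configurations no more probable than the observed one.
#'
#' @param n_homref,n_het,n_homalt genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_homref, n_het, n_homalt) {
  stopifnot(n_homref >= 0, n_het >= 0, n_homalt >= 0)
  n <- n_homref + n_het + n_homalt
  if (n == 0) stop("all genotypes missing: HWE test undefined")
  n_alt <- 2L * n_homalt + n_het                    # alt allele count
  hs <- seq(n_alt %% 2L, min(n_alt, 2L * n - n_alt), by = 2L)
  # log P(het = h | allele counts) up to a shared constant
  logp <-
    lfactorial(n) - lfactorial((n_alt - hs) / 2) - lfactorial(hs) -
    lfactorial(n - (n_alt + hs) / 2) + hs * log(2)
  logp <- logp - max(logp)
  pr <- exp(logp)
  pr <- pr / sum(pr)
  p_obs <- pr[match(n_het, hs)]
  min(1, sum(pr[pr <= p_obs * (1 + 1e-9)]))
}

#' Sample-level quality control
#'
#' Drops samples with a genotype call rate below the threshold or with a
#' transition/transversion, heterozygous/homozygous or insertion/deletion
#' ratio more than `ratio_outlier_sd` standard deviations from the cohort
#' mean. Means and SDs are computed once over the pre-drop cohort (no
#' iterative re-estimation); a zero or undefined SD flags no outliers.
#'
#' @param gt masked genotype matrix (variants x samples).
#' @param variants data.frame with `ref` and `alt` columns (used to class
#'   each variant as transition, transversion, insertion or deletion).
#' @param thresholds list from [qc_thresholds()].
#' @return list with `keep` (character vector of retained sample ids) and
#'   `metrics` (per-sample call rate and ratios with drop flags).
#' @export
sample_qc <- function(gt, variants, thresholds = qc_thresholds()) {
  t <- thresholds
  if (ncol(gt) < 2) stop("sample QC requires at least 2 samples")
  ids <- colnames(gt)
  if (is.null(ids)) ids <- paste0("S", seq_len(ncol(gt)))
  callrate <- colMeans(!is.na(gt))

  snv <- nchar(variants$ref) == 1 & nchar(variants$alt) == 1
  ti_pairs <- c("AG", "GA", "CT", "TC")
  klass <- ifelse(!snv,
                  ifelse(nchar(variants$alt) > nchar(variants$ref),
                         "ins", "del"),
                  ifelse(paste0(variants$ref, variants$alt) %in% ti_pairs,
                         "ti", "tv"))
  nonref <- !is.na(gt) & gt > 0L
  count_class <- function(k) colSums(nonref & klass == k)
  ti <- count_class("ti"); tv <- count_class("tv")
  ins <- count_class("ins"); del <- count_class("del")
  het <- colSums(gt == 1L, na.rm = TRUE)
  hom <- colSums(gt == 2L, na.rm = TRUE)
  safe_ratio <- function(a, b) ifelse(b > 0, a / b, NA_real_)
  ratios <- cbind(titv = safe_ratio(ti, tv),
                  hethom = safe_ratio(het, hom),
                  insdel = safe_ratio(ins, del))

  outlier <- rep(FALSE, length(ids))
  for (j in seq_len(ncol(ratios))) {
    r <- ratios[, j]
    m <- mean(r, na.rm = TRUE)
    s <- stats::sd(r, na.rm = TRUE)
    if (is.na(s) || s == 0) next
    outlier <- outlier | (!is.na(r) & abs(r - m) > t$ratio_outlier_sd * s)
  }
  low_cr <- callrate < t$sample_callrate_min
  metrics <- data.frame(sample_id = ids, call_rate = callrate, ratios,
                        low_callrate = low_cr, ratio_outlier = outlier,
                        dropped = low_cr | outlier,
                        row.names = NULL, stringsAsFactors = FALSE)
  list(keep = ids[!metrics$dropped], metrics = metrics)
}

#' Variant-level quality control
#'
#' Retains variants that are polymorphic, have a call rate of at least
#' `variant_callrate_min`, an exact Hardy-Weinberg p-value of at least
#' `hwe_p_min`, and a minor allele frequency (from non-missing calls)
#' below `maf_max`.
#'
#' @param gt masked genotype matrix (variants x samples).
#' @param thresholds list from [qc_thresholds()].
#' @return list with `keep` (logical vector over variants) and `metrics`
#'   (per-variant call rate, MAF, HWE p, filter flags).
#' @export
variant_qc <- function(gt, thresholds = qc_thresholds()) {
  t <- thresholds
  n <- ncol(gt)
  nm <- rowSums(!is.na(gt))
  callrate <- nm / n
  ac <- rowSums(gt, na.rm = TRUE)
  af <- ifelse(nm > 0, ac / (2 * nm), NA_real_)
  maf <- pmin(af, 1 - af)
  hwe <- vapply(seq_len(nrow(gt)), function(i) {
    g <- gt[i, ]
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    hwe_exact_p(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
  poly <- !is.na(af) & af > 0 & af < 1
  keep <- poly & callrate >= t$variant_callrate_min &
    !is.na(hwe) & hwe >= t$hwe_p_min &
    maf < t$maf_max
  metrics <- data.frame(call_rate = callrate, maf = maf, hwe_p = hwe,
                        polymorphic = poly, keep = keep,
                        row.names = rownames(gt))
  list(keep = keep, metrics = metrics)
}

#' Principal components of standardized genotype dosages
#'
#' Centers each variant at twice its allele frequency and scales by
#' `sqrt(2 f (1 - f))` before taking the top-`k` singular structure.
#' Missing dosages are mean-imputed (zero after centering); constant
#' variants are skipped. Sample scores are orthogonal by construction.
#'
#' @param gt genotype matrix (variants x samples).
#' @param k number of components.
#' @return list with `scores` (samples x k), `loadings` (variants x k),
#'   `d` (singular values), `varprop` (variance proportions).
#' @export
pca_genotypes <- function(gt, k = 10L) {
  nm <- rowSums(!is.na(gt))
  af <- rowSums(gt, na.rm = TRUE) / (2 * pmax(nm, 1))
  usable <- nm > 0 & af > 0 & af < 1
  if (sum(usable) < 1) stop("no polymorphic variants for PCA")
  g <- gt[usable, , drop = FALSE]
  f <- af[usable]
  z <- (g - 2 * f) / sqrt(2 * f * (1 - f))
  z[is.na(z)] <- 0
  k_eff <- min(k, nrow(z), ncol(z))
  if (k_eff < k)
    warning("requested k = ", k, " exceeds rank; using k = ", k_eff)
  sv <- svd(t(z), nu = k_eff, nv = k_eff)
  scores <- sv$u[, seq_len(k_eff), drop = FALSE] %*%
    diag(sv$d[seq_len(k_eff)], k_eff)
  colnames(scores) <- paste0("PC", seq_len(k_eff))
  rownames(scores) <- colnames(gt)
  loadings <- sv$v[, seq_len(k_eff), drop = FALSE]
  colnames(loadings) <- paste0("PC", seq_len(k_eff))
  list(scores = scores, loadings = loadings, d = sv$d,
       varprop = sv$d[seq_len(k_eff)]^2 / sum(sv$d^2))
}

#' Ancestry assignment from reference principal-component coordinates
#'
#' Trains a class-conditional Gaussian classifier (linear discriminant
#' analysis, pooled covariance) on labelled reference samples in PC space
#' and assigns each study sample the reference label only when the maximum
#' posterior probability exceeds `prob_min`; otherwise the sample is
#' `"unclassified"`.
#'
#' @param scores matrix of study-sample PC coordinates.
#' @param ref_scores matrix of reference PC coordinates (same columns).
#' @param ref_labels factor/character labels for `ref_scores` rows.
#' @param prob_min posterior threshold for assignment.
#' @return data.frame with `label` and `posterior` per study sample.
#' @export
assign_ancestry <- function(scores, ref_scores, ref_labels, prob_min = 0.8) {
  ref_labels <- as.factor(ref_labels)
  if (nlevels(droplevels(ref_labels)) < 2)
    stop("reference must contain at least 2 ancestry classes")
  if (any(table(ref_labels) == 0)) stop("empty reference class")
  fit <- MASS::lda(x = as.matrix(ref_scores), grouping = ref_labels)
  pr <- stats::predict(fit, as.matrix(scores))$posterior
  best <- max.col(pr, ties.method = "first")
  post <- pr[cbind(seq_len(nrow(pr)), best)]
  lab <- colnames(pr)[best]
  lab[post <= prob_min] <- "unclassified"
  data.frame(label = lab, posterior = post, stringsAsFactors = FALSE)
}

#' Identity-by-state kinship proxy (optional relatedness pruning)
#'
#' Computes pairwise mean identity-by-state similarity
#' (1 - |g_i - g_j| / 2, averaged over variants non-missing in both
#' samples) and greedily drops one sample from each pair above the
#' threshold. On a rare-variant panel most unrelated pairs sit near 1,
#' so the default threshold targets duplicates and first-degree
#' relatives, who share rare alleles; this is a proxy, not a kinship
#' estimator, and is off by default in the pipeline.
#'
#' @param gt genotype matrix (variants x samples).
#' @param threshold IBS similarity above which a pair is flagged.
#' @return list with `keep` (sample ids), `flagged_pairs` (data.frame
#'   of sample pairs and their IBS).
#' @export
kinship_prune <- function(gt, threshold = 0.99) {
  n <- ncol(gt)
  ids <- colnames(gt)
  if (is.null(ids)) ids <- paste0("S", seq_len(n))
  g <- gt
  obs <- !is.na(g)
  g[!obs] <- 0
  # sum |gi - gj| over shared non-missing sites, via the expansion
  # sum gi^2 + sum gj^2 - 2 sum gi gj on 0/1/2 dosages is not |.|;
  # use indicator decomposition instead: |a-b| over {0,1,2} equals
  # (a != b) + (|a-b| == 2)
  lev <- lapply(0:2, function(v) (gt == v) & obs)
  same <- matrix(0, n, n)
  for (v in 1:3) same <- same + crossprod(lev[[v]])
  far <- crossprod(lev[[1]], lev[[3]])
  far <- far + t(far)
  shared <- crossprod(obs)
  diff_sum <- (shared - same) + far       # sum |gi - gj|
  ibs <- 1 - diff_sum / (2 * pmax(shared, 1))
  flag <- which(upper.tri(ibs) & ibs > threshold & shared > 0,
                arr.ind = TRUE)
  pairs <- data.frame(sample_1 = ids[flag[, 1]],
                      sample_2 = ids[flag[, 2]],
                      ibs = ibs[flag], stringsAsFactors = FALSE)
  drop <- character(0)
  for (k in seq_len(nrow(pairs))) {
    if (pairs$sample_1[k] %in% drop || pairs$sample_2[k] %in% drop) next
    drop <- c(drop, pairs$sample_2[k])    # keep the first of each pair
  }
  list(keep = setdiff(ids, drop), flagged_pairs = pairs)
}

#' Genomic-control inflation factor
#'
#' \eqn{\lambda_{GC}}: the median of the chi-squared(1) quantiles of the
#' p-values divided by the null median 0.4549364. Values near 1 indicate
#' no inflation of the association statistics, e.g. from residual
#' population stratification.
#'
#' @param p vector of p-values in (0, 1].
#' @return lambda_GC.
#' @export
genomic_control_lambda <- function(p) {
  p <- p[!is.na(p)]
  if (length(p) == 0) stop("no p-values supplied")
  stopifnot(all(p > 0), all(p <= 1))
  chi <- stats::qchisq(p, df = 1, lower.tail = FALSE)
  stats::median(chi) / stats::qchisq(0.5, df = 1)
}

#' Vectorized single-variant score-test scan
#'
#' Per-variant score test of association between allele dosage and a
#' binary phenotype, with optional covariate adjustment by projecting both
#' phenotype and dosages off the covariate column space. Used as the
#' engine of the inflation diagnostic on common-variant null scans.
#'
#' @param gt genotype matrix (variants x samples), no missing values
#'   (mean-impute beforehand if needed).
#' @param y binary phenotype vector.
#' @param covariates optional numeric matrix of covariates (an intercept is
#'   always included).
#' @return data.frame with per-variant `chisq` and `p`.
#' @export
score_scan <- function(gt, y, covariates = NULL) {
  n <- length(y)
  C <- if (is.null(covariates)) matrix(1, n, 1)
       else cbind(1, as.matrix(covariates))
  qc <- qr(C)
  r_y <- stats::residuals(stats::lm.fit(C, y))
  G <- t(gt)                                   # samples x variants
  r_g <- G - qr.fitted(qc, G)
  u <- drop(crossprod(r_g, r_y))
  sigma2 <- sum(r_y^2) / n
  v <- sigma2 * colSums(r_g^2)
  chisq <- ifelse(v > 0, u^2 / v, NA_real_)
  data.frame(chisq = chisq,
             p = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

#' Filter variants by BED intervals
#'
#' BED intervals are 0-based, half-open; variant positions are 1-based.
#' With `polarity = "remove_inside"` variants falling in any interval are
#' removed (the convention for low-complexity-region masks); with
#' `"keep_inside"` only variants inside an interval are retained.
#'
#' @param variants data.frame with `chrom` and `pos` (1-based) columns.
#' @param bed data.frame with `chrom`, `start`, `end` (0-based half-open),
#'   e.g. from [read_bed()].
#' @param polarity `"remove_inside"` or `"keep_inside"`.
#' @return logical vector: variants retained.
#' @export
apply_region_mask <- function(variants, bed,
                              polarity = c("remove_inside", "keep_inside")) {
  polarity <- match.arg(polarity)
  inside <- rep(FALSE, nrow(variants))
  pos0 <- variants$pos - 1L                     # to 0-based
  for (ch in unique(bed$chrom)) {
    b <- bed[bed$chrom == ch, , drop = FALSE]
    sel <- which(variants$chrom == ch)
    if (!length(sel) || !nrow(b)) next
    for (i in seq_len(nrow(b)))
      inside[sel] <- inside[sel] |
        (pos0[sel] >= b$start[i] & pos0[sel] < b$end[i])
  }
  if (polarity == "remove_inside") !inside else inside
}

#' Read a BED file (0-based, half-open intervals)
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                 !startsWith(lines, "track")]
  parts <- strsplit(lines, "\t| +")
  bad <- which(vapply(parts, length, integer(1)) < 3)
  if (length(bad))
    stop("malformed BED line ", bad[1], ": fewer than 3 fields")
  out <- data.frame(
    chrom = vapply(parts, `[`, "", 1),
    start = suppressWarnings(as.integer(vapply(parts, `[`, "", 2))),
    end = suppressWarnings(as.integer(vapply(parts, `[`, "", 3))),
    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end) || any(out$end < out$start))
    stop("malformed BED line: non-numeric or inverted interval")
  out
}
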