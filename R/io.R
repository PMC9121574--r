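# Cohort file I/O: VCF 4.2 with GT:AD:DP:GQ genotypes plus TSV tables for
# demographics, ICD events, annotations and the ICD -> PheCode map.

#' Write a simulated cohort to disk
#'
#' Emits `cohort.vcf` (VCF 4.2, per-genotype GT:AD:DP:GQ, per-variant
#' GENE INFO tag), `demographics.tsv`, `icd_events.tsv`,
#' `annotations.tsv` and `icd_map.tsv`. The files round-trip losslessly
#' through [read_cohort()].
#'
#' @param cohort result of [simulate_cohort()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the named vector of written paths.
#' @export
write_cohort <- function(cohort, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE))
      stop("cannot create output directory: ", out_dir)
  paths <- c(vcf = file.path(out_dir, "cohort.vcf"),
             demographics = file.path(out_dir, "demographics.tsv"),
             icd_events = file.path(out_dir, "icd_events.tsv"),
             annotations = file.path(out_dir, "annotations.tsv"),
             icd_map = file.path(out_dir, "icd_map.tsv"))
  write_cohort_vcf(cohort$gt, cohort$variants, cohort$ad_ref,
                   cohort$ad_alt, cohort$dp, cohort$gq, paths["vcf"])
  wt <- function(x, p) utils::write.table(
    x, p, sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$demographics, paths["demographics"])
  wt(cohort$icd_events, paths["icd_events"])
  wt(cohort$annotations, paths["annotations"])
  wt(cohort$icd_map, paths["icd_map"])
  invisible(paths)
}

#' Write genotypes as VCF 4.2
#'
#' @param gt variants x samples dosage matrix (0/1/2, `NA` missing).
#' @param variants data.frame with chrom, pos, ref, alt, gene, variant_id.
#' @param ad_ref,ad_alt,dp,gq per-call matrices (optional; defaults fill
#'   consistent values).
#' @param path output path.
#' @export
write_cohort_vcf <- function(gt, variants, ad_ref = NULL, ad_alt = NULL,
                             dp = NULL, gq = NULL, path) {
  m <- nrow(gt); n <- ncol(gt)
  if (is.null(dp)) dp <- matrix(100L, m, n)
  if (is.null(gq)) gq <- matrix(99L, m, n)
  if (is.null(ad_alt)) ad_alt <- matrix(as.integer(round(dp * gt / 2)), m, n)
  if (is.null(ad_ref)) ad_ref <- dp - ad_alt
  gt_str <- matrix(c("0/0", "0/1", "1/1")[gt + 1L], m, n)
  gt_str[is.na(gt)] <- "./."
  cell <- matrix(paste(gt_str, paste(ad_ref, ad_alt, sep = ","),
                       dp, gq, sep = ":"), m, n)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rvburden",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Panel gene\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,Description=",
           "\"Allelic depths for the ref and alt alleles\">"),
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", colnames(gt)), collapse = "\t"))
  body <- paste(variants$chrom, variants$pos, variants$variant_id,
                variants$ref, variants$alt, ".", "PASS",
                paste0("GENE=", variants$gene), "GT:AD:DP:GQ",
                apply(cell, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a cohort VCF (GT:AD:DP:GQ)
#'
#' @param path VCF path.
#' @return list with `gt`, `variants`, `ad_ref`, `ad_alt`, `dp`, `gq`
#'   shaped as [simulate_genotypes()] output.
#' @export
read_cohort_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gene <- sub("^.*GENE=([^;]+).*$", "\\1", v@fix[, "INFO"])
  gene[!grepl("GENE=", v@fix[, "INFO"])] <- NA_character_
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  to_dosage <- function(g) {
    d <- rep(NA_integer_, length(g))
    d[g %in% c("0/0", "0|0")] <- 0L
    d[g %in% c("0/1", "1/0", "0|1", "1|0")] <- 1L
    d[g %in% c("1/1", "1|1")] <- 2L
    d
  }
  gt <- matrix(to_dosage(gt_raw), nrow(gt_raw), ncol(gt_raw),
               dimnames = dimnames(gt_raw))
  num_el <- function(el) {
    x <- vcfR::extract.gt(v, element = el)
    matrix(suppressWarnings(as.integer(x)), nrow(x), ncol(x),
           dimnames = dimnames(x))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  ad_ref <- matrix(suppressWarnings(
    as.integer(sub(",.*$", "", ad))), nrow(ad), ncol(ad),
    dimnames = dimnames(ad))
  ad_alt <- matrix(suppressWarnings(
    as.integer(sub("^[^,]*,", "", ad))), nrow(ad), ncol(ad),
    dimnames = dimnames(ad))
  variants <- data.frame(variant_id = fx$ID, chrom = fx$CHROM,
                         pos = as.integer(fx$POS), ref = fx$REF,
                         alt = fx$ALT, gene = gene,
                         stringsAsFactors = FALSE)
  rownames(gt) <- variants$variant_id
  list(gt = gt, variants = variants, ad_ref = ad_ref, ad_alt = ad_alt,
       dp = num_el("DP"), gq = num_el("GQ"))
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir the directory.
#' @return list with the genotype bundle plus `demographics`,
#'   `icd_events`, `annotations`, `icd_map`.
#' @export
read_cohort <- function(dir) {
  rt <- function(name, colClasses = NA) utils::read.table(
    file.path(dir, name), header = TRUE, sep = "\t",
    stringsAsFactors = FALSE, colClasses = colClasses)
  g <- read_cohort_vcf(file.path(dir, "cohort.vcf"))
  ann <- rt("annotations.tsv",
            colClasses = c(rep("character", 3), rep("character", 7),
                           "logical"))
  c(g, list(
    demographics = rt("demographics.tsv"),
    icd_events = rt("icd_events.tsv",
                    colClasses = c("character", "character", "integer",
                                   "character")),
    annotations = ann,
    icd_map = rt("icd_map.tsv",
                 colClasses = c("character", "integer", "character"))))
}
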