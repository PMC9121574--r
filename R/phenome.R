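# ICD -> PheCode phenome construction and curation.

#' Map ICD diagnosis events to PheCode events
#'
#' Joins diagnosis events to an ICD-to-PheCode mapping on the
#' (code, version) pair. A code mapping to several PheCodes emits one
#' event per mapped PheCode; unmapped codes emit nothing and are tallied
#' in a report.
#'
#' @param events data.frame with `sample_id`, `icd_code`, `icd_version`
#'   (9 or 10) and `date` columns.
#' @param mapping data.frame with `icd_code`, `icd_version`, `phecode`.
#' @return list with `events` (sample_id, phecode, date) and `unmapped`
#'   (unique unmapped code/version pairs with event counts).
#' @export
map_icd_to_phecode <- function(events, mapping) {
  req <- c("icd_code", "icd_version", "phecode")
  if (!all(req %in% names(mapping)) ||
      anyNA(mapping$icd_code) || anyNA(mapping$phecode))
    stop("malformed mapping table: need complete icd_code/icd_version/phecode")
  if (!all(events$icd_version %in% c(9, 10)))
    stop("icd_version must be 9 or 10")
  key_e <- paste(events$icd_code, events$icd_version, sep = "|")
  key_m <- paste(mapping$icd_code, mapping$icd_version, sep = "|")
  hit <- key_e %in% key_m
  merged <- merge(
    data.frame(sample_id = events$sample_id, key = key_e,
               date = events$date, stringsAsFactors = FALSE),
    data.frame(key = key_m, phecode = as.character(mapping$phecode),
               stringsAsFactors = FALSE),
    by = "key")
  unmapped <- if (any(!hit)) {
    u <- as.data.frame(table(key = key_e[!hit]), stringsAsFactors = FALSE)
    stats::setNames(u, c("icd_key", "n_events"))
  } else {
    data.frame(icd_key = character(), n_events = integer())
  }
  list(events = data.frame(sample_id = merged$sample_id,
                           phecode = merged$phecode,
                           date = merged$date, stringsAsFactors = FALSE),
       unmapped = unmapped)
}

#' Call case/control status from PheCode events
#'
#' A sample is a case for a PheCode when it has at least two events of
#' that PheCode on two different calendar dates; everyone else is a
#' control. Robust to duplicated event rows and event order. Optional
#' per-code exclusion lists remove named samples from a code's denominator
#' (status `NA`), default off.
#'
#' @param phecode_events data.frame with `sample_id`, `phecode`, `date`.
#' @param samples character vector of all analyzed sample ids.
#' @param exclusions optional named list: per phecode, sample ids to set
#'   to `NA` (excluded from that code's denominator).
#' @return a "phenome matrix": integer matrix samples x phecodes with
#'   1 = case, 0 = control, `NA` = excluded.
#' @export
call_case_status <- function(phecode_events, samples, exclusions = NULL) {
  ev <- unique(phecode_events[, c("sample_id", "phecode", "date")])
  codes <- sort(unique(as.character(ev$phecode)))
  mat <- matrix(0L, length(samples), length(codes),
                dimnames = list(samples, codes))
  if (nrow(ev)) {
    key <- paste(ev$sample_id, ev$phecode, sep = "|")
    ndates <- tapply(as.character(ev$date), key,
                     function(d) length(unique(d)))
    case_keys <- names(ndates)[ndates >= 2]
    if (length(case_keys)) {
      parts <- strsplit(case_keys, "|", fixed = TRUE)
      sid <- vapply(parts, `[`, "", 1)
      ph <- vapply(parts, `[`, "", 2)
      ok <- sid %in% samples
      mat[cbind(match(sid[ok], samples), match(ph[ok], codes))] <- 1L
    }
  }
  if (!is.null(exclusions)) {
    for (code in names(exclusions)) {
      if (!code %in% codes) next
      ex <- intersect(exclusions[[code]], samples)
      mat[match(ex, samples), code] <- NA_integer_
    }
  }
  mat
}

#' Curate PheCodes by minimum case count
#'
#' Retains PheCodes with at least `min_cases` cases and reports case
#' counts and in-sample prevalence (cases over that code's non-excluded
#' denominator).
#'
#' @param phenome phenome matrix from [call_case_status()].
#' @param min_cases minimum case count for retention.
#' @return data.frame per PheCode: `phecode`, `n_case`, `n_total`,
#'   `prevalence`, `kept`.
#' @export
curate_phecodes <- function(phenome, min_cases = 75L) {
  n_case <- colSums(phenome == 1L, na.rm = TRUE)
  n_total <- colSums(!is.na(phenome))
  data.frame(phecode = colnames(phenome),
             n_case = as.integer(n_case),
             n_total = as.integer(n_total),
             prevalence = n_case / n_total,
             kept = n_case >= min_cases,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pairwise Spearman correlations between PheCode case indicators
#'
#' @param phenome phenome matrix from [call_case_status()].
#' @param codes optional subset of PheCodes.
#' @return symmetric correlation matrix; pairs involving a constant
#'   indicator are `NA`.
#' @export
phenotype_correlations <- function(phenome, codes = NULL) {
  m <- phenome
  if (!is.null(codes)) m <- m[, codes, drop = FALSE]
  if (ncol(m) < 2) stop("need at least 2 PheCodes")
  suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
}
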