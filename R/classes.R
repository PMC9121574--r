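# Functional classification of coding consequences and assembly of the
# five qualifying-variant categories per gene.

.ptv_terms <- c(
  "disruptive_inframe_insertion", "disruptive_inframe_deletion",
  "frameshift_variant", "splice_acceptor_variant", "splice_donor_variant",
  "stop_gained", "feature_ablation", "exon_loss_variant")

.missense_terms <- c(
  "inframe_insertion", "inframe_deletion", "missense_variant",
  "splice_region_variant", "stop_lost", "start_lost",
  "coding_sequence_variant")

#' Classify a predicted consequence term into a functional class
#'
#' Maps annotation-tool consequence terms (SnpEff vocabulary) onto the
#' functional classes used by the burden categories: protein-truncating
#' (PTV), missense, synonymous, or other. Matching is exact and
#' case-sensitive; unknown terms fall through to `"other"`.
#' `"splice_region_variant"` is deliberately counted in the missense class.
#'
#' @param term character vector of consequence terms.
#' @return character vector in `{"ptv", "missense", "synonymous", "other"}`.
#' @export
classify_consequence <- function(term) {
  out <- rep("other", length(term))
  out[term %in% .ptv_terms] <- "ptv"
  out[term %in% .missense_terms] <- "missense"
  out[term == "synonymous_variant"] <- "synonymous"
  out
}

#' Seven-predictor damaging-missense consensus
#'
#' A missense variant is called damaging only when all seven in-silico
#' deleteriousness predictors call it deleterious (`"D"`). Any benign
#' (`"B"`) or missing (`NA`) call breaks the consensus — the strict rule
#' favors specificity.
#'
#' @param calls character matrix (variants x 7 predictors) with values
#'   `"D"`, `"B"` or `NA`; or a length-7 vector for a single variant.
#' @param consequence_class optional class vector from
#'   [classify_consequence()]; the consensus is only defined for missense
#'   variants and an error is raised otherwise.
#' @return logical vector.
#' @export
is_damaging_missense <- function(calls, consequence_class = NULL) {
  if (is.null(dim(calls))) calls <- matrix(calls, nrow = 1)
  if (ncol(calls) != 7)
    stop("expected 7 predictor calls, got ", ncol(calls))
  if (!is.null(consequence_class) && any(consequence_class != "missense"))
    stop("damaging-missense consensus applies to missense variants only")
  apply(calls, 1, function(r) all(!is.na(r) & r == "D"))
}

#' Assemble the five qualifying-variant categories per gene
#'
#' From QC-passed rare variants and their annotations, builds for every
#' gene the five nested variant sets entering burden scores: all rare
#' variants; non-synonymous (PTV plus missense); PTV; damaging missense
#' (all-7 predictor consensus); and PTV plus damaging missense. Variants
#' without a gene assignment are excluded and reported.
#'
#' @param annotations data.frame with columns `variant_id`, `gene`,
#'   `consequence_term`, and seven predictor columns named in
#'   `predictor_cols` with values `"D"`/`"B"`/`NA`.
#' @param variant_ids optional character vector restricting to QC-passed
#'   variants.
#' @param predictor_cols names of the seven predictor columns.
#' @return list with `sets` — a data.frame (gene, category, variant_id) —
#'   and `unassigned`, the variant ids lacking a gene.
#' @export
build_qualifying_sets <- function(annotations,
                                  variant_ids = NULL,
                                  predictor_cols = paste0("pred", 1:7)) {
  a <- annotations
  if (!is.null(variant_ids)) a <- a[a$variant_id %in% variant_ids, , drop = FALSE]
  unassigned <- a$variant_id[is.na(a$gene) | !nzchar(a$gene)]
  a <- a[!(is.na(a$gene) | !nzchar(a$gene)), , drop = FALSE]
  cls <- classify_consequence(a$consequence_term)
  calls <- as.matrix(a[, predictor_cols, drop = FALSE])
  dmg <- rep(FALSE, nrow(a))
  mis <- cls == "missense"
  if (any(mis)) dmg[mis] <- is_damaging_missense(calls[mis, , drop = FALSE])

  member <- list(
    all_rare = rep(TRUE, nrow(a)),
    nonsynonymous = cls %in% c("ptv", "missense"),
    ptv = cls == "ptv",
    damaging_missense = dmg,
    ptv_plus_damaging = cls == "ptv" | dmg
  )
  sets <- do.call(rbind, lapply(names(member), function(cat) {
    sel <- member[[cat]]
    if (!any(sel)) return(NULL)
    data.frame(gene = a$gene[sel], category = cat,
               variant_id = a$variant_id[sel], stringsAsFactors = FALSE)
  }))
  if (is.null(sets))
    sets <- data.frame(gene = character(), category = character(),
                       variant_id = character(), stringsAsFactors = FALSE)
  list(sets = sets, unassigned = unassigned)
}

#' Qualifying-variant categories
#'
#' The five categories of qualifying variants entering burden scores.
#' @return character vector of category names.
#' @export
qualifying_categories <- function() {
  c("all_rare", "nonsynonymous", "ptv", "damaging_missense",
    "ptv_plus_damaging")
}

#' Extract one gene x category variant set
#'
#' @param qsets result of [build_qualifying_sets()].
#' @param gene,category the cell wanted.
#' @return character vector of variant ids (possibly empty).
#' @export
qualifying_variants <- function(qsets, gene, category) {
  s <- qsets$sets
  s$variant_id[s$gene == gene & s$category == category]
}
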