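# Burden scores, carrier (dominance) tests, the PheWAS grid, interaction
# and gene-set scans, GO over-representation, and multiplicity control.

#' Per-sample burden score over a qualifying-variant set
#'
#' Sum of alternate-allele counts across the set's variants; missing
#' genotypes contribute 0 (no dosage imputation).
#'
#' @param gt genotype matrix (variants x samples) with variant ids as
#'   row names.
#' @param variant_ids the qualifying set.
#' @return numeric vector, one score per sample.
#' @export
burden_score <- function(gt, variant_ids) {
  if (length(variant_ids) == 0) stop("empty qualifying set")
  sel <- rownames(gt) %in% variant_ids
  colSums(gt[sel, , drop = FALSE], na.rm = TRUE)
}

#' Carrier indicator: at least one qualifying alternate allele
#'
#' @inheritParams burden_score
#' @return logical vector per sample.
#' @export
carrier_flag <- function(gt, variant_ids) {
  burden_score(gt, variant_ids) >= 1
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Exact p summing hypergeometric probabilities (margins fixed) of every
#' table with point probability no greater than the observed table's, and
#' the crude odds ratio `ad/bc` with a Haldane 0.5 continuity correction
#' applied to all cells whenever any cell is zero. A zero margin makes the
#' table degenerate: p = 1 and the odds ratio undefined.
#'
#' @param a,b,c,d cell counts: carriers/non-carriers among cases (a, b)
#'   and among controls (c, d).
#' @return list with `p`, `or`, `degenerate`.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  stopifnot(a >= 0, b >= 0, c >= 0, d >= 0)
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0)
    return(list(p = 1, or = NA_real_, degenerate = TRUE))
  m1 <- a + b      # cases
  m2 <- c + d      # controls
  k <- a + c       # carriers
  xs <- max(0, k - m2):min(k, m1)
  pr <- stats::dhyper(xs, m1, m2, k)
  p_obs <- pr[match(a, xs)]
  p <- min(1, sum(pr[pr <= p_obs * (1 + 1e-7)]))
  or <- if (a == 0 || b == 0 || c == 0 || d == 0)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  else (a * d) / (b * c)
  list(p = p, or = or, degenerate = FALSE)
}

.drop_incomplete_covariates <- function(covariates) {
  keep <- stats::complete.cases(covariates)
  if (!all(keep))
    message("dropping ", sum(!keep), " sample(s) with missing covariates")
  keep
}

# covariate model matrix (reference-coded site indicators), minus intercept
.covariate_matrix <- function(covariates) {
  cv <- as.data.frame(covariates)
  if ("site" %in% names(cv)) cv$site <- factor(cv$site)
  # constant covariates (e.g. a single-site cohort) carry no information
  const <- vapply(cv, function(x) length(unique(x[!is.na(x)])) < 2,
                  logical(1))
  cv <- cv[, !const, drop = FALSE]
  if (ncol(cv) == 0)
    return(matrix(1, nrow(as.data.frame(covariates)), 1,
                  dimnames = list(NULL, "(Intercept)")))
  stats::model.matrix(~ ., cv)
}

# one burden test: Firth PLR on the burden term + Fisher on carriers
.burden_test_cell <- function(y, burden, covX, level = 0.95) {
  ok <- !is.na(y)
  y <- y[ok]; b <- burden[ok]; X <- covX[ok, , drop = FALSE]
  carrier <- b >= 1
  n_case <- sum(y == 1); n_control <- sum(y == 0)
  cc <- sum(carrier & y == 1); ctc <- sum(carrier & y == 0)
  fish <- fisher_exact_2x2(cc, n_case - cc, ctc, n_control - ctc)
  Xb <- cbind(X, burden = b)
  res <- tryCatch({
    plr <- firth_plr_test(Xb, y, term = "burden")
    ci <- tryCatch(firth_wald_ci(plr$fit_full, "burden", level = level),
                   error = function(e) c(or = NA, lower = NA, upper = NA))
    list(or = unname(ci["or"]), lo = unname(ci["lower"]),
         hi = unname(ci["upper"]), p = plr$p_value,
         conv = plr$fit_full$converged && plr$fit_null$converged)
  }, error = function(e) list(or = NA_real_, lo = NA_real_, hi = NA_real_,
                              p = NA_real_, conv = FALSE))
  data.frame(n_case = n_case, n_control = n_control,
             case_carriers = cc, control_carriers = ctc,
             or_firth = res$or, ci_lower = res$lo, ci_upper = res$hi,
             p_firth = res$p, converged = res$conv,
             or_fisher = fish$or, p_fisher = fish$p)
}

.empty_cell <- function() {
  data.frame(n_case = NA_integer_, n_control = NA_integer_,
             case_carriers = NA_integer_, control_carriers = NA_integer_,
             or_firth = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_,
             p_firth = NA_real_, converged = NA,
             or_fisher = NA_real_, p_fisher = NA_real_)
}

#' Run the primary PheWAS burden grid
#'
#' For every (PheCode x gene x category) cell, regresses case-control
#' status on the per-sample burden score with Firth logistic regression
#' adjusting for the supplied covariates, reporting the penalized
#' likelihood-ratio p-value, Wald odds ratio and interval, carrier counts
#' and the two-sided Fisher exact (dominance) p. Cells whose qualifying
#' set is empty, or whose qualifying variants are absent from the study
#' samples, are present in the grid but flagged untested.
#'
#' @param phenome phenome matrix from [call_case_status()] restricted to
#'   curated PheCodes; rows must align with `colnames(gt)` and
#'   `covariates`.
#' @param qsets qualifying sets from [build_qualifying_sets()].
#' @param gt QC-passed genotype matrix (variants x samples).
#' @param covariates data.frame of per-sample covariates (e.g. age, sex,
#'   site, PC1..PC10); `site` is treated as a factor.
#' @param genes genes forming the grid (defaults to genes present in
#'   `qsets`; pass the full panel to include never-qualifying genes).
#' @param categories qualifying categories forming the grid.
#' @return data.frame, one row per grid cell, with carrier counts, Firth
#'   and Fisher statistics and a `tested` flag.
#' @export
run_phewas <- function(phenome, qsets, gt, covariates,
                       genes = sort(unique(qsets$sets$gene)),
                       categories = qualifying_categories()) {
  keep <- .drop_incomplete_covariates(covariates)
  covariates <- covariates[keep, , drop = FALSE]
  gt <- gt[, keep, drop = FALSE]
  phenome <- phenome[keep, , drop = FALSE]
  covX <- .covariate_matrix(covariates)
  stopifnot(nrow(covX) == ncol(gt), nrow(phenome) == ncol(gt))
  codes <- colnames(phenome)
  if (length(codes) == 0)
    stop("phenome has no PheCodes to test")
  out <- vector("list", length(genes) * length(categories))
  i <- 0L
  for (gene in genes) {
    for (cat in categories) {
      i <- i + 1L
      vids <- qualifying_variants(qsets, gene, cat)
      burden <- if (length(vids)) burden_score(gt, vids) else NULL
      tested <- !is.null(burden) && any(burden > 0, na.rm = TRUE)
      if (tested) {
        cells <- do.call(rbind, lapply(codes, function(code)
          .burden_test_cell(phenome[, code], burden, covX)))
      } else {
        cells <- do.call(rbind, replicate(length(codes), .empty_cell(),
                                          simplify = FALSE))
      }
      out[[i]] <- cbind(data.frame(phecode = codes, gene = gene,
                                   category = cat, tested = tested,
                                   stringsAsFactors = FALSE), cells)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Interaction scan: burden x age or burden x sex
#'
#' Re-fits every tested grid cell adding a modifier-by-burden interaction
#' term to the primary model and reports the penalized likelihood-ratio
#' p-value for the interaction coefficient.
#'
#' @inheritParams run_phewas
#' @param modifier `"age"` or `"sex"` — must be a covariate column.
#' @return data.frame like [run_phewas()] with `p_interaction`.
#' @export
interaction_scan <- function(phenome, qsets, gt, covariates,
                             modifier = c("age", "sex"),
                             genes = sort(unique(qsets$sets$gene)),
                             categories = qualifying_categories()) {
  modifier <- match.arg(modifier)
  if (!modifier %in% colnames(covariates))
    stop("modifier '", modifier, "' not among covariates")
  mod <- covariates[[modifier]]
  if (length(unique(mod[!is.na(mod)])) < 2)
    stop("modifier '", modifier, "' is constant: interaction undefined")
  keep <- .drop_incomplete_covariates(covariates)
  covariates <- covariates[keep, , drop = FALSE]
  gt <- gt[, keep, drop = FALSE]
  phenome <- phenome[keep, , drop = FALSE]
  mod <- mod[keep]
  covX <- .covariate_matrix(covariates)
  codes <- colnames(phenome)
  out <- list()
  i <- 0L
  for (gene in genes) {
    for (cat in categories) {
      vids <- qualifying_variants(qsets, gene, cat)
      burden <- if (length(vids)) burden_score(gt, vids) else NULL
      tested <- !is.null(burden) && any(burden > 0, na.rm = TRUE)
      for (code in codes) {
        i <- i + 1L
        row <- data.frame(phecode = code, gene = gene, category = cat,
                          modifier = modifier, tested = tested,
                          p_interaction = NA_real_,
                          beta_interaction = NA_real_,
                          stringsAsFactors = FALSE)
        if (tested) {
          y <- phenome[, code]
          ok <- !is.na(y)
          Xb <- cbind(covX[ok, , drop = FALSE], burden = burden[ok],
                      burden_x_mod = burden[ok] * mod[ok])
          ans <- tryCatch({
            plr <- firth_plr_test(Xb, y[ok], term = "burden_x_mod")
            list(p = plr$p_value,
                 b = unname(plr$fit_full$coefficients["burden_x_mod"]))
          }, error = function(e) list(p = NA_real_, b = NA_real_))
          row$p_interaction <- ans$p
          row$beta_interaction <- ans$b
        }
        out[[i]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene-set burden PheWAS
#'
#' Aggregates qualifying variants across a set of genes (per category)
#' into one burden score and runs the same Firth and Fisher machinery as
#' the single-gene grid. For a singleton set this reduces exactly to the
#' single-gene result.
#'
#' @inheritParams run_phewas
#' @param set_genes member genes of the set.
#' @param set_id label used in the `gene` column of the result.
#' @return data.frame like [run_phewas()], one row per PheCode x category.
#' @export
gene_set_burden <- function(phenome, qsets, gt, covariates, set_genes,
                            set_id = "gene_set",
                            categories = qualifying_categories()) {
  if (length(set_genes) == 0) stop("empty gene set")
  keep <- .drop_incomplete_covariates(covariates)
  covariates <- covariates[keep, , drop = FALSE]
  gt <- gt[, keep, drop = FALSE]
  phenome <- phenome[keep, , drop = FALSE]
  covX <- .covariate_matrix(covariates)
  codes <- colnames(phenome)
  out <- list()
  i <- 0L
  for (cat in categories) {
    vids <- unique(unlist(lapply(set_genes, function(g)
      qualifying_variants(qsets, g, cat))))
    burden <- if (length(vids)) burden_score(gt, vids) else NULL
    tested <- !is.null(burden) && any(burden > 0, na.rm = TRUE)
    if (tested) {
      cells <- do.call(rbind, lapply(codes, function(code)
        .burden_test_cell(phenome[, code], burden, covX)))
    } else {
      cells <- do.call(rbind, replicate(length(codes), .empty_cell(),
                                        simplify = FALSE))
    }
    i <- i + 1L
    out[[i]] <- cbind(data.frame(phecode = codes, gene = set_id,
                                 category = cat, tested = tested,
                                 stringsAsFactors = FALSE), cells)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Gene Ontology over-representation test
#'
#' Hypergeometric upper-tail test per term: the probability of observing
#' at least the seen number of study genes in the term, given the term's
#' size in the background. Terms absent from the background are skipped.
#' Also reports, per domain, the minimal-p term with its member genes
#' intersected with the study set.
#'
#' @param study_genes character vector of study (panel) genes.
#' @param term_table data.frame with `term`, `domain` (one of
#'   "biological_process", "cellular_component", "molecular_function")
#'   and `gene` columns mapping background genes to terms.
#' @param background_size total number of background genes N.
#' @return list with `terms` (per-term k, K, p) and `top_per_domain`
#'   (minimal-p term per domain with `study_members`).
#' @export
go_overrepresentation <- function(study_genes, term_table,
                                  background_size) {
  study_genes <- unique(study_genes)
  n <- length(study_genes)
  N <- background_size
  terms <- unique(term_table[, c("term", "domain")])
  rows <- lapply(seq_len(nrow(terms)), function(i) {
    tg <- unique(term_table$gene[term_table$term == terms$term[i]])
    K <- length(tg)
    if (K == 0 || K > N) return(NULL)
    k <- length(intersect(tg, study_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = terms$term[i], domain = terms$domain[i],
               K = K, k = k, p = p, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  top <- lapply(split(tab, tab$domain), function(d) {
    best <- d[which.min(d$p), , drop = FALSE]
    best$study_members <- paste(sort(intersect(
      unique(term_table$gene[term_table$term == best$term]),
      study_genes)), collapse = ",")
    best
  })
  list(terms = tab, top_per_domain = do.call(rbind, top))
}

#' Multiplicity control: per-PheWAS Bonferroni and study-wide FDR
#'
#' Adds the per-PheWAS Bonferroni threshold (0.05 divided by the number
#' of distinct PheCodes in the grid), Benjamini-Hochberg q-values across
#' the tested cells, and suggestive / study-wide significance flags.
#' Untested cells are excluded from the FDR family by default.
#'
#' @param results grid from [run_phewas()].
#' @param alpha familywise level for the Bonferroni threshold and the FDR
#'   cutoff.
#' @param fdr_family `"tested"` (default) or `"all"`: whether the BH
#'   denominator counts untested cells.
#' @return `results` with `p_bonf_threshold`, `q_value`, `suggestive`,
#'   `study_wide` columns.
#' @export
adjust_multiplicity <- function(results, alpha = 0.05,
                                fdr_family = c("tested", "all")) {
  fdr_family <- match.arg(fdr_family)
  n_codes <- length(unique(results$phecode))
  thr <- alpha / n_codes
  results$p_bonf_threshold <- thr
  results$q_value <- NA_real_
  tested <- results$tested & !is.na(results$p_firth)
  m <- if (fdr_family == "all") nrow(results) else sum(tested)
  results$q_value[tested] <- stats::p.adjust(results$p_firth[tested],
                                             method = "BH", n = m)
  results$suggestive <- tested & results$p_firth < thr
  results$study_wide <- tested & !is.na(results$q_value) &
    results$q_value < alpha
  results
}
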