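test_that("burden scores sum alternate alleles, missing contributing 0", {
  gt <- rbind(v1 = c(1L, 0L, 2L), v2 = c(1L, NA, 0L), v3 = c(0L, 0L, 1L))
  colnames(gt) <- c("A", "B", "C")
  expect_equal(burden_score(gt, c("v1", "v2")),
               c(A = 2, B = 0, C = 2))
  expect_equal(burden_score(gt, "v1"), c(A = 1, B = 0, C = 2))
  expect_equal(carrier_flag(gt, c("v1", "v2")),
               c(A = TRUE, B = FALSE, C = TRUE))
  expect_error(burden_score(gt, character(0)), "empty")

  set.seed(41)
  big <- matrix(sample(c(0L, 1L, 2L, NA), 600, TRUE,
                       prob = c(0.8, 0.1, 0.05, 0.05)), 30, 20)
  rownames(big) <- paste0("w", 1:30)
  vids <- sample(rownames(big), 12)
  oracle <- apply(big[vids, ], 2, function(g) sum(g, na.rm = TRUE))
  expect_equal(burden_score(big, vids), oracle)
})

test_that("Fisher exact p matches base-R enumeration; crude OR is Haldane-corrected", {
  f <- fisher_exact_2x2(1, 9, 9, 1)
  expect_equal(f$p, fisher.test(matrix(c(1, 9, 9, 1), 2))$p.value,
               tolerance = 1e-12)
  # proportional table: observed is the modal table
  prop <- fisher_exact_2x2(5, 50, 10, 100)
  expect_equal(prop$or, 1)
  expect_equal(prop$p, 1)
  # Haldane correction when a cell is zero
  h <- fisher_exact_2x2(0, 10, 10, 10)
  expect_equal(h$or, (0.5 * 10.5) / (10.5 * 10.5))
  # zero margin: degenerate
  z <- fisher_exact_2x2(0, 0, 5, 5)
  expect_true(z$degenerate)
  expect_equal(z$p, 1)
  expect_true(is.na(z$or))

  set.seed(2)
  for (i in 1:200) {
    cells <- as.vector(rmultinom(1, sample(10:60, 1), runif(4)))
    expect_equal(fisher_exact_2x2(cells[1], cells[2], cells[3],
                                  cells[4])$p,
                 fisher.test(matrix(cells, 2, byrow = TRUE))$p.value,
                 tolerance = 1e-12)
  }
})

# small deterministic grid setup shared by grid tests
grid_fixture <- function(n = 600, seed = 51) {
  set.seed(seed)
  gt <- rbind(
    v1 = rbinom(n, 1, 0.05), v2 = rbinom(n, 1, 0.03),  # GENEA
    v3 = rbinom(n, 1, 0.04),                            # GENEB
    v4 = rep(0L, n))                                    # GENEC: absent
  colnames(gt) <- sprintf("S%03d", seq_len(n))
  ann <- data.frame(
    variant_id = c("v1", "v2", "v3", "v4"),
    gene = c("GENEA", "GENEA", "GENEB", "GENEC"),
    consequence_term = c("stop_gained", "missense_variant",
                         "stop_gained", "stop_gained"),
    stringsAsFactors = FALSE)
  preds <- matrix("D", 4, 7, dimnames = list(NULL, paste0("pred", 1:7)))
  ann <- cbind(ann, as.data.frame(preds))
  qsets <- build_qualifying_sets(ann)
  phen <- cbind(`296.2` = rbinom(n, 1, 0.2), `318` = rbinom(n, 1, 0.15))
  rownames(phen) <- colnames(gt)
  cov <- data.frame(age = rnorm(n, 55, 12), sex = rbinom(n, 1, 0.5),
                    site = sample(1:3, n, TRUE),
                    row.names = colnames(gt))
  list(gt = gt, qsets = qsets, phen = phen, cov = cov)
}

test_that("the grid is complete and untested cells are flagged", {
  fx <- grid_fixture()
  res <- run_phewas(fx$phen, fx$qsets, fx$gt, fx$cov,
                    genes = c("GENEA", "GENEB", "GENEC"))
  expect_equal(nrow(res), 2 * 3 * 5)
  # GENEC's only variant is absent in the samples -> untested
  expect_true(all(!res$tested[res$gene == "GENEC"]))
  # GENEB has no missense -> damaging_missense untested
  expect_false(any(res$tested[res$gene == "GENEB" &
                                res$category == "damaging_missense"]))
  tested <- res[res$tested, ]
  expect_true(all(is.finite(tested$p_firth)))
  expect_true(all(tested$case_carriers <= tested$n_case))
  expect_true(all(tested$control_carriers <= tested$n_control))
  # carrier counts agree with direct tabulation for one cell
  vids <- qualifying_variants(fx$qsets, "GENEA", "all_rare")
  carrier <- carrier_flag(fx$gt, vids)
  y <- fx$phen[, "296.2"]
  row <- res[res$gene == "GENEA" & res$category == "all_rare" &
               res$phecode == "296.2", ]
  expect_equal(row$case_carriers, sum(carrier & y == 1))
  expect_equal(row$control_carriers, sum(carrier & y == 0))
})

test_that("grid results are invariant to sample order", {
  fx <- grid_fixture(n = 300)
  perm <- sample(ncol(fx$gt))
  res1 <- run_phewas(fx$phen, fx$qsets, fx$gt, fx$cov, genes = "GENEA")
  res2 <- run_phewas(fx$phen[perm, ], fx$qsets, fx$gt[, perm],
                     fx$cov[perm, ], genes = "GENEA")
  expect_equal(res1$p_firth, res2$p_firth, tolerance = 1e-8)
  expect_equal(res1$case_carriers, res2$case_carriers)
})

test_that("samples with missing covariates are dropped for the fit", {
  fx <- grid_fixture(n = 300)
  fx$cov$age[1:5] <- NA
  expect_message(
    res <- run_phewas(fx$phen, fx$qsets, fx$gt, fx$cov, genes = "GENEA"),
    "5 sample")
  expect_equal(res$n_case[1] + res$n_control[1], 295)
})

test_that("BH q-values and Bonferroni threshold are correct", {
  # hand step-up: all q equal min over tail of p * m / rank
  fake <- data.frame(phecode = rep(sprintf("c%02d", 1:37), length.out = 4),
                     gene = "G", category = "all_rare", tested = TRUE,
                     p_firth = c(0.01, 0.02, 0.03, 0.04))
  fake$phecode <- sprintf("c%02d", 1:4)
  out <- adjust_multiplicity(fake)
  expect_equal(out$q_value, rep(0.04, 4))
  expect_equal(out$p_bonf_threshold, rep(0.05 / 4, 4))

  set.seed(61)
  p <- runif(50)^2
  fake2 <- data.frame(phecode = sprintf("c%02d", seq_along(p)), gene = "G",
                      category = "all_rare", tested = TRUE, p_firth = p)
  out2 <- adjust_multiplicity(fake2)
  expect_equal(out2$q_value, bh_oracle(p), tolerance = 1e-12)
  # monotone in p-rank
  expect_true(all(diff(out2$q_value[order(p)]) >= -1e-12))
  # Bonferroni-suggestive implies nominal
  expect_true(all(out2$p_firth[out2$suggestive] < 0.05))

  allnull <- fake2
  allnull$p_firth <- 1
  out3 <- adjust_multiplicity(allnull)
  expect_false(any(out3$suggestive) || any(out3$study_wide))
})

test_that("gene-set burden reduces to the single gene and is additive", {
  fx <- grid_fixture()
  single <- run_phewas(fx$phen, fx$qsets, fx$gt, fx$cov, genes = "GENEA")
  set1 <- gene_set_burden(fx$phen, fx$qsets, fx$gt, fx$cov,
                          set_genes = "GENEA", set_id = "GENEA_set")
  for (cat in qualifying_categories()) {
    s <- single[single$category == cat, ]
    g <- set1[set1$category == cat, ]
    expect_equal(s$p_firth, g$p_firth, tolerance = 1e-10)
    expect_equal(s$case_carriers, g$case_carriers)
  }
  # additivity of scores across disjoint genes
  va <- qualifying_variants(fx$qsets, "GENEA", "all_rare")
  vb <- qualifying_variants(fx$qsets, "GENEB", "all_rare")
  expect_equal(burden_score(fx$gt, c(va, vb)),
               burden_score(fx$gt, va) + burden_score(fx$gt, vb))
  expect_error(gene_set_burden(fx$phen, fx$qsets, fx$gt, fx$cov,
                               set_genes = character(0)), "empty")
})

test_that("interaction scan rejects constant modifiers and finds planted ones", {
  fx <- grid_fixture(n = 400)
  fx$cov$sex <- 1L
  expect_error(interaction_scan(fx$phen, fx$qsets, fx$gt, fx$cov,
                                modifier = "sex", genes = "GENEA"),
               "constant")

  # planted sex-specific effect: OR 4 in females, 1 in males
  set.seed(71)
  n <- 4000
  hits <- 0
  for (rep in 1:15) {
    carrier <- rbinom(n, 1, 0.05)
    sex <- rbinom(n, 1, 0.5)
    y <- rbinom(n, 1, plogis(-1 + log(4) * carrier * sex))
    X <- cbind(`(Intercept)` = 1, sex = sex, burden = carrier,
               bxs = carrier * sex)
    p <- firth_plr_test(X, y, "bxs")$p_value
    if (!is.na(p) && p < 1e-3) hits <- hits + 1
  }
  expect_gt(hits, 7)   # majority of replicates
})

test_that("interaction p-values are calibrated under no interaction", {
  set.seed(81)
  n <- 2000
  ps <- replicate(40, {
    carrier <- rbinom(n, 1, 0.05)
    age <- rnorm(n, 55, 12)
    y <- rbinom(n, 1, plogis(-1.5 + 0.5 * carrier))
    X <- cbind(1, age = age, burden = carrier, bxa = carrier * age)
    firth_plr_test(X, y, "bxa")$p_value
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("GO over-representation matches hypergeometric summation", {
  tt <- data.frame(
    term = c(rep("T1", 4), rep("T2", 8), rep("T3", 3)),
    domain = c(rep("biological_process", 4), rep("molecular_function", 8),
               rep("cellular_component", 3)),
    gene = c(paste0("G", 1:4), paste0("G", 3:10), paste0("H", 1:3)),
    stringsAsFactors = FALSE)
  study <- paste0("G", 1:4)
  res <- go_overrepresentation(study, tt, background_size = 50)
  t1 <- res$terms[res$terms$term == "T1", ]
  expect_equal(t1$k, 4)
  # brute-force upper-tail hypergeometric sum
  brute <- sum(dhyper(4:4, 4, 46, 4))
  expect_equal(t1$p, brute, tolerance = 1e-12)
  t2 <- res$terms[res$terms$term == "T2", ]
  expect_equal(t2$p, sum(dhyper(t2$k:min(8, 4), 8, 42, 4)),
               tolerance = 1e-12)
  # most enriched term wins its domain
  top_bp <- res$top_per_domain[
    res$top_per_domain$domain == "biological_process", ]
  expect_equal(top_bp$term, "T1")
  expect_equal(top_bp$study_members, "G1,G2,G3,G4")
  # degenerate: study = background = term
  deg <- go_overrepresentation(paste0("G", 1:4),
                               data.frame(term = "T", domain = "bp",
                                          gene = paste0("G", 1:4)),
                               background_size = 4)
  expect_equal(deg$terms$p, 1)
})
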