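# One-call matrices make the per-rule masking cases explicit.
one_call <- function(gt, ref, alt, dp = 30, gq = 99) {
  masked <- mask_genotypes(matrix(gt), matrix(ref), matrix(alt),
                           matrix(dp), matrix(gq))
  masked[1, 1]
}

test_that("genotype masking applies each AB/GQ/DP rule", {
  expect_true(is.na(one_call(0L, 88, 12, dp = 100)))   # hom-ref AB 0.12
  expect_equal(one_call(0L, 95, 5, dp = 100), 0L)      # hom-ref AB 0.05
  expect_equal(one_call(1L, 15, 15), 1L)               # het AB 0.5
  expect_true(is.na(one_call(1L, 24, 6)))              # het AB 0.2
  expect_true(is.na(one_call(1L, 6, 24)))              # het AB 0.8
  expect_true(is.na(one_call(2L, 5, 25)))              # hom-alt AB 0.83
  expect_equal(one_call(2L, 1, 29), 2L)                # hom-alt AB 0.97
  expect_true(is.na(one_call(1L, 15, 15, gq = 19)))    # GQ < 20
  expect_true(is.na(one_call(1L, 5, 4, dp = 9)))       # DP < 10
  expect_true(is.na(one_call(0L, 0, 0, dp = 30)))      # AB undefined
})

test_that("masking is idempotent and never resurrects a missing call", {
  set.seed(4)
  m <- 40; n <- 30
  gt <- matrix(sample(c(0L, 1L, 2L, NA), m * n, TRUE), m, n)
  dp <- matrix(rpois(m * n, 40), m, n)
  ad_alt <- matrix(rbinom(m * n, as.vector(dp), 0.4), m, n)
  ad_ref <- dp - ad_alt
  gq <- matrix(sample(0:99, m * n, TRUE), m, n)
  once <- mask_genotypes(gt, ad_ref, ad_alt, dp, gq)
  twice <- mask_genotypes(once, ad_ref, ad_alt, dp, gq)
  expect_identical(once, twice)
  expect_true(all(is.na(once[is.na(gt)])))
})

test_that("multiallelic split trims to minimal representation", {
  # second alt carries an inserted base; first equals the reference
  expect_warning(out <- split_and_left_trim("chr1", 100, "AT",
                                            c("AT", "ATT")),
                 "identical to reference")
  expect_equal(nrow(out), 1)
  # left-aligned minimal form of the T insertion
  expect_equal(out$pos, 100)
  expect_equal(out$ref, "A")
  expect_equal(out$alt, "AT")

  snv <- split_and_left_trim("chr2", 500, "G", "C")
  expect_equal(snv, split_and_left_trim(snv$chrom, snv$pos, snv$ref,
                                        snv$alt))
  expect_error(split_and_left_trim("chr1", 10, "A", "A"), "non-variant")
  # deletion: suffix trimmed, anchor base retained (VCF minimal form)
  del <- split_and_left_trim("chr3", 200, "CAGT", "CT")
  expect_equal(del$pos, 200)
  expect_equal(del$ref, "CAG")
  expect_equal(del$alt, "C")
  # both ends shared but a single differing base remains
  sub <- split_and_left_trim("chr3", 300, "CAT", "CGT")
  expect_equal(sub$pos, 301)
  expect_equal(sub$ref, "A")
  expect_equal(sub$alt, "G")
})

test_that("exact HWE p agrees with the recurrence oracle", {
  expect_equal(hwe_exact_p(100, 0, 0), 1)      # monomorphic
  expect_equal(hwe_exact_p(25, 50, 25), hwe_oracle(25, 50, 25),
               tolerance = 1e-12)
  # extreme heterozygote deficit: p near the minimum over configurations
  p_deficit <- hwe_exact_p(50, 0, 50)
  expect_equal(p_deficit, hwe_oracle(50, 0, 50), tolerance = 1e-12)
  expect_lt(p_deficit, 1e-20)
  set.seed(8)
  for (i in 1:100) {
    n <- sample(3:200, 1)
    g <- as.vector(rmultinom(1, n, prob = runif(3)))
    expect_equal(hwe_exact_p(g[1], g[2], g[3]),
                 hwe_oracle(g[1], g[2], g[3]), tolerance = 1e-12)
  }
  expect_error(hwe_exact_p(0, 0, 0), "undefined")
})

test_that("sample QC drops low call rate and ratio outliers once", {
  set.seed(12)
  m <- 200; n <- 40
  gt <- matrix(rbinom(m * n, 2, 0.2), m, n,
               dimnames = list(NULL, paste0("S", 1:n)))
  variants <- data.frame(ref = rep(c("A", "A", "AT", "A"), length.out = m),
                         alt = rep(c("G", "C", "A", "AG"), length.out = m))
  # S1: call rate 96%
  gt[sample(m, ceiling(0.04 * m) + 1), 1] <- NA
  res <- sample_qc(gt, variants)
  expect_false("S1" %in% res$keep)
  expect_true(res$metrics$low_callrate[1])

  # identical samples: zero SD, nobody dropped
  gt2 <- matrix(rep(rbinom(m, 2, 0.2), 10), m, 10,
                dimnames = list(NULL, paste0("T", 1:10)))
  res2 <- sample_qc(gt2, variants)
  expect_equal(res2$keep, paste0("T", 1:10))

  # one extreme het/hom outlier (~3x the cohort-mean ratio)
  gt3 <- matrix(rbinom(m * 100, 2, 0.25), m, 100,
                dimnames = list(NULL, paste0("U", 1:100)))
  gt3[, 1] <- c(rep(1L, m - 10), rep(2L, 10))
  res3 <- sample_qc(gt3, variants)
  expect_false("U1" %in% res3$keep)

  expect_error(sample_qc(gt[, 1, drop = FALSE], variants), "2 samples")
})

test_that("variant QC retains exactly the designed survivors", {
  n <- 2000
  mk <- function(n0, n1, n2, nmiss = 0) {
    c(rep(0L, n0), rep(1L, n1), rep(2L, n2), rep(NA, nmiss))[
      seq_len(n)]
  }
  gt <- rbind(
    good = mk(n - 30, 30, 0),                       # passes everything
    mono = mk(n, 0, 0),                             # monomorphic
    lowcall = c(mk(n - 130, 30, 0), rep(NA, 100))[
      c(seq_len(n - 100), (n - 99):n)],             # call rate 0.95 - eps
    hwe_fail = mk(n - 15, 0, 15),                   # het deficit
    common = mk(n - 100, 60, 40),                   # MAF 0.035
    good2 = mk(n - 10, 10, 0))
  gt["lowcall", ] <- c(mk(n - 30, 30, 0)[seq_len(n - 101)], rep(NA, 101))
  res <- variant_qc(gt)
  expect_equal(rownames(gt)[res$keep], c("good", "good2"))
  expect_false(res$metrics["mono", "polymorphic"])
  expect_lt(res$metrics["lowcall", "call_rate"], 0.95)
  expect_lt(res$metrics["hwe_fail", "hwe_p"], 1e-6)
  expect_gt(res$metrics["common", "maf"], 0.01)
})

test_that("variant QC is invariant to sample order", {
  set.seed(19)
  gt <- matrix(rbinom(50 * 400, 2, 0.004), 50, 400)
  perm <- sample(400)
  expect_equal(variant_qc(gt)$keep, variant_qc(gt[, perm])$keep)
})

test_that("PCA separates diverged subpopulations and is orthogonal", {
  set.seed(33)
  n <- 300; m <- 200
  subpop <- rep(1:2, each = n / 2)
  f <- cbind(runif(m, 0.05, 0.15), runif(m, 0.35, 0.6))  # diverged freqs
  gt <- sapply(seq_len(n), function(j) rbinom(m, 2, f[, subpop[j]]))
  pca <- pca_genotypes(gt, k = 4)
  pc1 <- pca$scores[, 1]
  r1 <- range(pc1[subpop == 1])
  r2 <- range(pc1[subpop == 2])
  expect_true(r1[2] < r2[1] || r2[2] < r1[1])   # zero overlap
  gram <- crossprod(pca$scores)
  expect_lt(max(abs(gram[upper.tri(gram)])), 1e-8)

  # permuted genotypes: no separation beyond chance
  gp <- t(apply(gt, 1, sample))
  pcp <- pca_genotypes(gp, k = 2)$scores[, 1]
  sep <- abs(mean(pcp[subpop == 1]) - mean(pcp[subpop == 2]))
  expect_lt(sep, sd(pcp))

  expect_warning(pca_genotypes(gt[1:3, ], k = 10), "rank")
})

test_that("ancestry assignment respects the posterior threshold", {
  set.seed(6)
  half <- matrix(rnorm(200, mean = 5, sd = 0.5), 100, 2)
  ref <- rbind(-half, half)    # exactly symmetric classes
  labels <- rep(c("EUR", "AFR"), each = 100)
  at_centroid <- assign_ancestry(matrix(c(-5, -5), 1, 2), ref, labels)
  expect_equal(at_centroid$label, "EUR")
  expect_gt(at_centroid$posterior, 0.99)
  # equidistant between two equal-prior classes
  midpoint <- assign_ancestry(matrix(c(0, 0), 1, 2), ref, labels)
  expect_equal(midpoint$label, "unclassified")
  expect_lte(midpoint$posterior, 0.5 + 1e-9)

  study <- rbind(matrix(rnorm(300, -5, 0.8), 150, 2),
                 matrix(rnorm(300, 5, 0.8), 150, 2))
  truth <- rep(c("EUR", "AFR"), each = 150)
  got <- assign_ancestry(study, ref, labels)
  classified <- got$label != "unclassified"
  expect_gte(mean(got$label[classified] == truth[classified]), 0.95)

  expect_error(assign_ancestry(study, ref, rep("EUR", 200)), "2 ancestry")
})

test_that("kinship proxy flags duplicates and keeps one of each pair", {
  set.seed(17)
  gt <- matrix(rbinom(400 * 25, 2, 0.05), 400, 25,
               dimnames = list(NULL, paste0("S", 1:25)))
  gt[, 2] <- gt[, 1]
  gt[5, 2] <- NA
  kp <- kinship_prune(gt)
  expect_equal(kp$flagged_pairs$sample_1, "S1")
  expect_equal(kp$flagged_pairs$sample_2, "S2")
  expect_true("S1" %in% kp$keep)
  expect_false("S2" %in% kp$keep)
  # unrelated samples on a rare panel sit below the duplicate threshold
  expect_equal(length(kp$keep), 24)
})

test_that("lambda_GC has its closed form and scale equivariance", {
  expect_equal(genomic_control_lambda(rep(0.5, 7)), 1.0)
  set.seed(44)
  stats <- rchisq(5000, df = 1)
  p1 <- pchisq(stats, 1, lower.tail = FALSE)
  p2 <- pchisq(2 * stats, 1, lower.tail = FALSE)
  expect_equal(genomic_control_lambda(p2),
               2 * genomic_control_lambda(p1), tolerance = 1e-10)
  p_unif <- runif(10000)
  l <- genomic_control_lambda(p_unif)
  expect_gt(l, 0.95); expect_lt(l, 1.05)
  expect_error(genomic_control_lambda(numeric(0)), "no p-values")
})

test_that("region masking follows half-open BED semantics", {
  bed <- data.frame(chrom = "chr1", start = 90, end = 110)
  v <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                  pos = c(100, 110, 111, 100))
  keep <- apply_region_mask(v, bed, "remove_inside")
  expect_equal(keep, c(FALSE, FALSE, TRUE, TRUE))  # pos 110 -> 0-based 109
  expect_equal(apply_region_mask(v, bed, "keep_inside"), !keep)

  set.seed(13)
  vr <- data.frame(chrom = sample(c("chr1", "chr2"), 300, TRUE),
                   pos = sample(1:1000, 300, TRUE))
  bedr <- data.frame(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                     start = sample(0:900, 20))
  bedr$end <- bedr$start + sample(10:80, 20, TRUE)
  expect_equal(apply_region_mask(vr, bedr), mask_oracle(vr, bedr))

  bad <- tempfile()
  writeLines(c("chr1\t10\t20", "chr1\t5"), bad)
  expect_error(read_bed(bad), "malformed")
  good <- tempfile()
  writeLines("chr1\t10\t20", good)
  expect_equal(read_bed(good),
               data.frame(chrom = "chr1", start = 10L, end = 20L))
})
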