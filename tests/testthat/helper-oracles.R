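# Independent oracles used across the suite. Each deliberately takes a
# different computational path from the implementation it checks.

# Exact HWE p by Wigginton-style recurrence over heterozygote counts
# (the implementation uses direct log-gamma evaluation instead).
hwe_oracle <- function(n_homref, n_het, n_homalt) {
  n <- n_homref + n_het + n_homalt
  n_alt <- 2 * n_homalt + n_het
  n_ref <- 2 * n - n_alt
  rare <- min(n_alt, n_ref)
  hs <- seq(rare %% 2, rare, by = 2)
  probs <- numeric(length(hs))
  mid <- length(hs)
  probs[mid] <- 1
  # downward recurrence from the maximal het count
  for (i in rev(seq_len(length(hs) - 1))) {
    h <- hs[i + 1]
    hom_r <- (rare - h) / 2           # rare-allele homozygotes at h
    hom_c <- n - h - hom_r
    probs[i] <- probs[i + 1] * h * (h - 1) /
      (4 * (hom_r + 1) * (hom_c + 1))
  }
  probs <- probs / sum(probs)
  obs_h <- min(n_het, rare)           # observed het in rare-allele terms
  p_obs <- probs[match(n_het, hs)]
  sum(probs[probs <= p_obs * (1 + 1e-9)])
}

# Hand step-up Benjamini-Hochberg
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# Brute-force interval membership (O(n*m))
mask_oracle <- function(variants, bed, polarity = "remove_inside") {
  inside <- vapply(seq_len(nrow(variants)), function(i) {
    p0 <- variants$pos[i] - 1
    any(bed$chrom == variants$chrom[i] & p0 >= bed$start & p0 < bed$end)
  }, logical(1))
  if (polarity == "remove_inside") !inside else inside
}

# Haldane half-cell-corrected log odds ratio (Firth 2x2 closed form)
haldane_log_or <- function(a, b, c, d) {
  log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
}

# Expand a 2x2 carrier table into response/design vectors
table_to_xy <- function(a, b, c, d) {
  list(y = c(rep(1, a + b), rep(0, c + d)),
       x = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}

# Small cohort config used by several suites
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_samples = 400L, n_genes = 4L, variants_per_gene = 15L,
         maf_law_spec = maf_law("loguniform", 1e-3, 9e-3),
         phecode_specs = data.frame(
           phecode = c("296.2", "318", "295.1"),
           prevalence = c(0.15, 0.18, 0.05),
           loading = c(0.5, 0.4, 0.5)),
         seed = 11L),
    list(...))
  do.call(cohort_config, args)
}
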