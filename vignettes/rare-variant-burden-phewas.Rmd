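---
title: "Methods: rare-variant burden PheWAS with Firth regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant burden PheWAS with Firth regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rvburden` implements a phenome-wide gene-burden analysis of rare coding
variation in a targeted sequencing panel, from raw genotype calls to a
multiplicity-controlled association grid. This vignette documents the
statistical model, the defaults and the numerical choices, and what the
bundled synthetic-cohort generator does and does not emulate.

## The burden model

For gene $g$, qualifying category $c$ and PheCode $k$, the per-sample
burden score is the sum of alternate alleles across the qualifying set;
missing genotypes contribute zero (no dosage imputation — conservative,
and unbiased toward the null). Case status is regressed on the burden
with Firth-penalized logistic regression,

$$\ell^*(\beta) = \ell(\beta) + \tfrac12 \log\det\{X^\top W X\},
\qquad W = \mathrm{diag}\{\pi_i(1-\pi_i)\},$$

adjusting for age, sex, reference-coded site indicators, and the first
10 principal components of the standardized genotype matrix. The
Jeffreys-prior penalty keeps estimates finite under complete
separation — the operative regime when a gene has a handful of
carriers — and removes the leading-order small-sample bias of the MLE.
The reported p-value is the penalized likelihood-ratio (PLR) test: the
constrained fit holds the burden coefficient at zero, re-maximizes all
other coefficients, and recomputes the determinant penalty from the
full design, so the two penalized log-likelihoods are nested. A
two-sided Fisher exact test on carrier counts (at least one qualifying
allele; a dominance coding) accompanies every cell as a model-free
cross-check.

Assumptions worth stating: additivity of allele effects within a
category (the burden collapses all qualifying variants into one
count with equal weights); no attempt at recessive or
compound-heterozygote models; covariates act on the logit scale; and
cases and controls come from one population after ancestry-restricted
QC, with residual stratification absorbed by the PCs and checked by the
genomic-control factor $\lambda_{GC}$.

## Qualifying-variant categories

Consequence terms are matched case-sensitively against fixed
vocabularies: the PTV class (stop-gain, frameshift, essential splice,
exon loss, feature ablation, disruptive inframe indels), the missense
class (missense, inframe indels, start/stop loss, coding-sequence,
splice-region — the splice-region term is deliberately counted here,
following the classification the panel analysis uses), synonymous, and
everything else. A missense variant is *damaging* only when all seven
deleteriousness predictors call it deleterious; a missing predictor
call breaks the consensus (strict — favors specificity, at the cost of
sensitivity when annotation is incomplete). The five categories per
gene form a lattice: all rare $\supseteq$ non-synonymous $\supseteq$
missense $\supseteq$ damaging missense, with PTV+damaging = PTV
$\cup$ damaging missense. Cells whose qualifying set is empty, or
whose qualifying alleles are absent among the analyzed samples, are
kept in the grid but flagged untested and excluded from the FDR family
(a flag widens the family to all cells if wanted). Multi-transcript
annotation collapse is the caller's responsibility; when a variant
carries several terms the most severe one should be supplied.

## Quality control

Defaults (all overridable via `qc_thresholds()`):

| parameter | default | meaning |
|---|---|---|
| `ab_homref_max` | 0.10 | max allelic balance for hom-ref calls |
| `ab_het_min`, `ab_het_max` | 0.25, 0.75 | het allelic-balance window |
| `ab_homalt_min` | 0.90 | min allelic balance for hom-alt calls |
| `gq_min`, `dp_min` | 20, 10 | per-call genotype quality / depth floors |
| `sample_callrate_min` | 0.975 | sample retention floor |
| `ratio_outlier_sd` | 3 | Ts/Tv, het/hom, ins/del outlier cut (SD) |
| `variant_callrate_min` | 0.95 | variant retention floor |
| `hwe_p_min` | 1e-6 | exact Hardy-Weinberg floor |
| `maf_max` | 0.01 | rare-variant ceiling (exclusive) |
| `ancestry_prob_min` | 0.8 | posterior needed to assign an ancestry |

Choices the thresholds do not settle: calls with zero informative reads
have undefined allelic balance and are set to missing (consistent with
the depth filter's intent); ratio-outlier means and SDs are computed
once over the pre-drop cohort, not iteratively; the exact HWE test is
applied to all retained samples after masking; multiallelic sites are
split per alternate allele and trimmed to minimal representation
(suffix first, then prefix, always keeping an anchor base) — full
left-shifting against a reference sequence is out of scope since panel
VCFs often ship without one. Region masks are BED, 0-based half-open;
the polarity is a flag with default *remove variants inside* the
intervals, the usual convention for low-complexity-region masks.
Ancestry assignment uses a class-conditional Gaussian (pooled
covariance, i.e. linear discriminant) posterior on reference PC
coordinates; the contract is the 0.8 posterior threshold, not the
specific learner, so any classifier producing class posteriors can be
substituted. An individual at the midpoint of two equal-prior classes
has posterior 0.5 and stays unclassified. Relatedness handling is a
mean identity-by-state proxy (`kinship_prune()`, default threshold
0.99, off by default): on a rare-variant panel unrelated pairs sit
near-indistinguishably close to IBS 1, so the proxy reliably catches
duplicates and close relatives who share rare alleles but is not a
kinship estimator; pedigree-grade pruning needs common markers the
panel may not carry.

## Phenome construction

ICD-9/ICD-10 events are joined to a user-supplied mapping (a code may
map to several PheCodes; unmapped codes are tallied, not dropped
silently). A sample is a case for a PheCode when it has events on at
least two distinct calendar dates; everyone else is a control.
One-event samples therefore count as controls — the mapping of
"possible cases" to controls is a deliberate default, and per-code
exclusion lists are available (default off) for analyses that prefer
excluding them from the denominator. Dates are compared at calendar-day
granularity. PheCodes with fewer than 75 cases (an in-sample prevalence
of 0.5% at the reference cohort size) are dropped from the analysis
grid.

## Multiplicity

Within one gene's PheWAS the suggestive threshold is
$0.05 / \#\text{curated PheCodes}$; study-wide significance is
Benjamini-Hochberg FDR $< 0.05$ across all tested grid cells. With 37
curated codes the per-PheWAS threshold is $1.35\times10^{-3}$ and a
58-gene, 5-category grid has $37 \times 58 \times 5 = 10{,}730$ cells.

## Numerical choices in the Firth engine

Newton-Raphson on the modified score
$U^*_r = \sum_i x_{ir}\{y_i - \pi_i + h_i(\tfrac12 - \pi_i)\}$, with
leverages $h_i$ from the weighted hat matrix, computed via Cholesky
factorization of $X^\top W X$. Steps that would decrease $\ell^*$ are
halved (up to ~20 times). Convergence requires max $|U^*| < 10^{-6}$
*and* max $|\Delta\beta| < 10^{-8}$, within 100 iterations — mirroring
widely used Firth implementations; non-convergence is flagged on the
returned object and PLR p-values from flagged fits are reported as
missing rather than trusted. Rank-deficient design columns are dropped
with a warning before fitting. On any 2×2 table the Firth slope equals
the Haldane half-cell-corrected log odds ratio, which the tests verify
to $10^{-8}$; on information-rich data the estimates converge to the
unpenalized MLE (relative difference below 1% at $n = 10^5$ in the
suite). Wald intervals are the default (`confint(..., type =
"profile")` inverts the PLR test by bisection instead); both are
provided because the interval method behind published burden tables is
typically unstated, and neither is treated as an exactness surface.

## The synthetic-cohort generator

Defaults describe the study conditions the pipeline targets: 58 panel
genes, ~224 rare variants per gene (~13,000 total), minor allele
frequencies log-uniform below 1% (hard-capped by construction), a
~15,000-sample cohort recruited across 10 sites, 54.5% women, ages
6-100 with a right-skewed age distribution (median ≈ 62), and
per-call fields from a shifted-Poisson depth law with mean 500×.
Small contamination fractions (0.5% low-GQ calls, 0.5% calls with
genotype-discordant allele fractions) give the masking rules
non-trivial work while keeping per-sample call rates realistically
above the 0.975 retention floor — at 500× depth, binomial read-count
noise alone essentially never violates the allelic-balance windows, so
discordant reads must be injected explicitly. Consequence terms are
drawn from a configurable class mix (default 10% PTV, 45% missense,
25% synonymous, 20% other); each of the seven predictors agrees with a
latent deleterious flag independently with probability 0.9, so the
all-7 consensus recovers $0.9^7 \approx 48\%$ of truly deleterious
missense variants.

Phenotypes follow a liability-threshold-free logistic model: the case
probability is $\mathrm{expit}$ of an intercept (calibrated numerically
so the marginal prevalence matches the spec), age/sex/site effects, a
loading on one shared standard-normal factor per sample — the simplest
mechanism reproducing the positively skewed pairwise correlations of
real psychiatric phenomes — and any planted burden effects
($\beta \times$ burden, additive or dominant). Cases emit two ICD
codes on distinct dates; a configurable 10% emit only one, exercising
the two-date rule's censoring. Controls emit nothing for that code.

What the generator does *not* emulate: linkage disequilibrium and
haplotype structure (variants are independent), sequencing reads,
X-chromosome dosage and sex checks, relatedness, correlation between
consequence class and allele length, within-gene clustering of
deleterious variants, and the visit-process structure of real EHR data
(event dates are uniform, not clustered by encounter). Passing tests
therefore demonstrate statistical correctness of the pipeline under
its own assumptions, not robustness to these real-data features.
Because frequencies are capped below 1%, subpopulation perturbation
produces only weak PC structure; the PCA and ancestry operations are
validated on directly constructed common-variant dosages instead,
which is the regime those steps face in practice (real panels include
common spike-in SNVs for exactly this purpose).

## Problem sizes in the test suite

The suite exercises the full chain at sizes chosen to make each check
statistically meaningful while staying desk-scale: the Firth 2×2
equivalence on 100+ random tables; PLR type-I error over 1,000 null
replicates at $n = 2{,}000$ with 1% carriers (accepted band 3-7% at
$\alpha = 5\%$); planted-effect recovery (log-OR 1.5, 10% prevalence)
over 20 replicates at $n = 15{,}000$; all-null cohorts over 20
replicates at $n = 2{,}500$ with zero study-wide FDR discoveries
expected in ≥95%; and $\lambda_{GC}$ on a 3,000-variant null scan of a
30%-prevalence trait at $n = 10{,}000$, expected in $[0.9, 1.1]$.
Exact-test implementations are compared against independent
enumeration oracles (recurrence-based HWE, base-R `fisher.test`, hand
step-up BH) to $10^{-12}$.

## Known limitations

Single-variant association is provided only as a score-test scan for
the inflation diagnostic; SKAT-type variance-component tests, recessive
models, kinship adjustment and mixed models are out of scope. The
burden test's power degrades when a category mixes risk and protective
alleles, by construction of the equal-weight collapse. Full-scale
default cohorts (15,181 × 13,000 with four per-call matrices) need
several GB of memory; the pipeline stages run comfortably at the
reduced sizes above, and nothing in the methods depends on the scale.
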