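---
title: "Epistatic SNP interaction networks for quantitative traits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Epistatic SNP interaction networks for quantitative traits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wishnet)
```

## The problem

Single-marker genome-wide association leaves much of the genetic variance
of complex quantitative traits — feed efficiency in livestock being a
canonical example — unexplained. Part of that gap is epistasis: the effect
of an allele at one locus depends on the genotype at another. `wishnet`
implements a complete desk-to-results pipeline for finding *epistatic SNP
modules*: groups of SNPs whose pairwise interaction effects on a trait
form a coherent network community, summarized by an eigenSNP and related
back to the trait.

The pipeline is: genotype QC → single-SNP association → top-K pre-filter →
LD-block pruning → exhaustive pairwise interaction regression → signed
weighted network → topological-overlap module detection → module
eigenSNP–trait correlation → hub-SNP extraction → positional gene
annotation. A seeded simulator generates genotype/phenotype worlds with
planted effects and the ground truth needed to validate every stage.

## The model

For every pair of SNPs $(i, j)$, coded as minor-allele dosage
$g \in \{0, 1, 2\}$, we fit by ordinary least squares

$$ y = \mu + \beta_1 g_i + \beta_2 g_j + \beta_3 (g_i g_j) + \epsilon $$

and test $\beta_3$ — the epistatic effect — two-sided with
$t = \hat\beta_3 / \mathrm{se}(\hat\beta_3)$ on $n - 4$ degrees of
freedom, complete-case per pair. The scan is batched: all cross-product
sums entering the $4 \times 4$ normal equations come from a handful of
matrix products over the missingness-masked dosage matrix, and each
pair's system is solved directly. A per-pair QR fitter
(`fit_pair_model()`) provides the independent route; the two agree to
$10^{-14}$ and the test suite asserts $10^{-8}$.

The $\beta_3$ matrix becomes a *signed weighted network*:
$s_{ij} = \beta_{3,ij} / \max|\beta_3|$, then
$a_{ij} = ((1 + s_{ij})/2)^\beta$. Failed fits (collinear or too few
complete cases) get the neutral weight $s = 0$. Topological overlap
$\mathrm{TOM}_{ij} = (\sum_u a_{iu}a_{uj} + a_{ij}) /
(\min(k_i, k_j) + 1 - a_{ij})$ converts shared neighborhoods into
similarity, and modules are branches of the average-linkage tree of
$1 - \mathrm{TOM}$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| sample call rate | remove if ≤ 0.90 | per-sample genotyping rate |
| SNP call rate | remove if < 0.90 | per-SNP genotyping rate |
| MAF minimum | 0.01 | monomorphic/rare SNP filter |
| HWE p | < 1e-7 | exact-test departure filter |
| `top_k` | 7000 | SNPs carried into the pairwise scan |
| `ld_threshold` | 0.9 | r² to the block representative |
| `max_block_size` | 1000 | LD-block cap |
| `quantile` | 0.9 | chromosome-pair overview quantile of −log10 p |
| `power_beta` | 12 | soft-threshold power of the signed transform |
| `min_module_size` | 30 | smallest admissible module |
| `merge_cut_height` | 0.25 | merge modules with eigenSNP cor ≥ 0.75 |
| `r_min`, `p_max` | 0.4, 0.05 | module–trait selection gates (|r|, raw p) |
| `top_n_modules` | 3 | modules carried to hub extraction |

Note the deliberately asymmetric call-rate operators (samples `<=`,
SNPs `<`): they follow the conventional QC phrasing for this kind of
array study. Per-SNP statistics (minor allele, MAF, HWE) are recomputed
after sample filtering on the analyzed subset, which is why group-level
QC counts differ from whole-cohort counts.

### Phenotypes

Feed conversion ratio is the exact ratio FCR = FC/DW (feed consumed over
weight gain; *high* FCR = *low* efficiency, so the high tail is the LFE
group). Residual feed intake is the residual of an OLS regression of
daily feed intake on production covariates; the covariate set is
configurable (default: daily gain and initial weight) because the
originating protocol is not fully specified in the literature this
design follows. Efficiency groups seed at mean ± 1 SD of FCR and fill to
exactly `n_per_group` by extremity rank, with sample-id tie-breaks from
opposite ends so even fully degenerate inputs yield disjoint groups.

## Design choices where the design was open

**Network weights.** The network is built from normalized $\beta_3$
coefficients, not from $-\log_{10} p$: the coefficients are the
"epistatic correlation" quantity the framework propagates, and using
them preserves sign information for the signed transform. A
99.5th-percentile normalization is available for outlier-heavy matrices
(`normalization = "quantile"`).

**Soft-threshold power.** The default is the signed-network convention
$\beta = 12$. A scale-free-fit chooser (`pick_power()`) is provided, but
on desk-scale planted matrices it selects powers (~6) too soft to
separate module from background — the scale-free criterion is a
heuristic for large empirical networks, not small simulations — so the
pipeline does not auto-pick unless asked (`power_beta = NULL`).

**Tree cut.** The reference dynamic hybrid tree cut is re-stated here as
a deterministic two-part rule: cut the average-linkage tree at the mean
off-diagonal dissimilarity (a module must cohere more tightly than the
average SNP pair), then keep only clusters with ≥ `min_module_size`
members whose mean within-cluster dissimilarity is ≤ 0.99 of the
background mean. The 0.99 gate is calibrated to the near-1 TOM
dissimilarities of estimated interaction matrices: genuine modules sit a
few percent below background, while the large loose clusters average
linkage forms on pure noise stay within a fraction of a percent of it
(pure-noise inputs come out entirely grey). The procedure has no
randomness: fixed input gives an identical partition on every run.

**LD blocks.** Block membership is chained against the block's *first*
member (the representative), not all members — O(n) per chromosome and
faithful to "block" semantics. Pruning keeps each block's
most-associated member. Because the original tool's internal rule is not
published, full-data pruned counts may diverge; the chain rule is the
documented contract.

**Multiplicity.** Bonferroni adjustment runs over all module × trait
cells; the selection gate uses raw p (≤ 0.05) with |r| > 0.4, reporting
the adjusted value alongside, because with 10–30 modules the adjusted
threshold would contradict the stated gate.

## What the simulator emulates — and what it does not

`simulate_genotypes()` uses a Gaussian-copula construction: one latent
AR(1) normal per LD block per sample, thresholded at the Hardy–Weinberg
genotype quantiles of each SNP's target MAF. SNPs of one block share a
base MAF up to jitter (SD 0.01) — alleles in strong LD co-segregate, and
without this the dichotomization caps attainable genotype r² well below
the latent correlation. Blocks are independent, positions uniform,
missingness uniform at `missing_rate`.

`simulate_phenotypes()` draws the trait from the pairwise interaction
model itself (planted mains and pairs plus Gaussian noise), rescales
affinely to an FCR-like mean 1.96, SD 0.07 (the Duroc scale of the
motivating design), back-fills FC and DW so that FC/DW reproduces the
trait exactly, and generates daily intake as linear in daily gain plus a
trait-linked residual so that RFI carries signal.

Not emulated: demography, selection, pedigree/kinship structure,
genotyping-platform error modes, chromosome-scale recombination maps. A
green recovery test therefore establishes that the *pipeline machinery*
recovers structure of the stated kind and strength — not that real pig
data contains such structure.

**Known limitation — power at small n.** With ~60 samples, the per-pair
$\hat\beta_3$ standard error leaves individual interactions near the
noise floor; planted-module recovery through the *full* pipeline
(estimation included) is unreliable at n = 60 and the corresponding
integration test runs at n = 150, where recovery succeeds in ≥ 9/10
seeds. Module recovery from a given coefficient matrix (the
planted-partition benchmark, within-module β₃ ~ N(0.8, 0.1) vs
background N(0, 0.05)) succeeds at ARI = 1 in 10/10 seeds at size 500.
Real cohorts of this size buy power through dense LD and many
participating pairs, which the desk-scale worlds only partially mimic.

## Numerical choices

- HWE exact p: stable log-space recurrence over heterozygote counts;
  two-sided by summing outcomes with probability ≤ observed (with a
  1e-12 relative slack for ties); validated exhaustively against direct
  enumeration for every table up to 100 samples.
- Minor-allele ties at MAF exactly 0.5 go to the lexicographically
  smaller allele — deterministic and file-dialect independent.
- Quantiles everywhere are type-7 (linear interpolation), stated because
  the chromosome-pair overview is a quantile map.
- Batched pair fits are flagged collinear when the Cholesky of the
  normal matrix fails or the inverse is numerically unbounded; the QR
  route uses rank detection. Exactly collinear designs (e.g., a SNP
  paired with itself) are flagged identically by both.
- EigenSNPs: missing dosages mean-imputed, columns z-scored, first left
  singular vector scaled to SD 1, sign anchored to correlate
  non-negatively with the mean standardized dosage, so allele-coding
  flips change nothing observable downstream.

## Validation surface

The test suite asserts, among others: batched-vs-QR equality (≤ 1e-8,
30 random instances); null type-I fraction 0.05 ± 0.01 over ≥ 12,000
pairs; β₃ bias within 2 Monte-Carlo SEs over 500 replicates and exact
(≤ 1e-10) noiseless recovery; planted two-module ARI ≥ 0.8 in ≥ 8/10
seeds; HWE-vs-enumeration ≤ 1e-12 exhaustively to 100 samples; and hub
tables whose row counts equal the sum of selected module sizes.
`scripts/acceptance.R` recomputes all of these from scratch against the
installed package and writes them as JSON.
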