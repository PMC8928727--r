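---
title: "Sum-based enrichment of GWAS signals in gene sets: model and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sum-based enrichment of GWAS signals in gene sets: model and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sumenrich)
```

## The question the package answers

Transcriptome experiments produce gene sets — differentially expressed
genes (DEGs) stratified by fold-change bin, or co-expression modules —
and a GWAS on the same population produces a per-SNP effect size for
each trait. `sumenrich` asks: *do the SNPs falling inside a given gene
set carry more association signal for a trait than a random stretch of
genome of the same size and shape?* A positive answer ties the
expression program to the genetic architecture of the trait.

## The enrichment statistic and its null

For a gene set $S$, every SNP lying inside a member gene's body or
within 5 kb up- or downstream of it is flagged; $m_g$ is the number of
flagged SNPs. The statistic is the sum of squared per-SNP effects

$$T_{\mathrm{sum}} = \sum_{i=1}^{m_g} \beta_i^2 ,$$

where $\beta_i$ is the raw mixed-model effect estimate (a standardized
$(\beta/se)^2$ variant is available via `statistic = "z"`, but raw
effects are the default because the statistic is defined on the
marker-effect scale).

Significance comes from a circular-rotation permutation: concatenate
the chromosomes into a circle in canonical order, draw an offset $k$
uniform on $\{1, \dots, n_{\mathrm{snp}} - 1\}$, rotate the whole
membership mask by $k$, and recompute $T_{\mathrm{sum}}$ with the
effect vector held fixed. Every rotation preserves both $m_g$ and the
mask's local clustering, so the null respects the correlation of
effects among neighbouring SNPs (LD) that independent SNP resampling
would destroy. With $B$ rotations the one-tailed empirical p-value is

$$p = \frac{1 + \#\{T^{(b)} \ge T_{\mathrm{obs}}\}}{B + 1},$$

which counts ties against significance and can never reach zero; its
smallest attainable value is $1/(B+1)$. The default is $B = 10{,}000$.

Two closed-form facts anchor the implementation and are asserted in the
tests: the mean of the exhaustive rotation distribution equals
$(m_g / n_{\mathrm{snp}}) \sum_i \beta_i^2$ exactly, and for a toy
panel of four SNPs with effects $(1,2,3,4)$ and a two-SNP mask the
nonzero rotations give exactly the support $\{13, 25, 17\}$.

Design choices that were genuinely open:

* **Genome-wide versus per-chromosome rotation.** Genome-wide rotation
  is the default (one circle over all chromosomes); it has many more
  distinct offsets and treats chromosome ends as the only artificial
  junctions. `per_chromosome = TRUE` rotates each chromosome
  independently instead.
* **Offset 0** (the identity) is excluded from the draws — it is the
  observed statistic — and the $+1$ in the estimator re-includes it
  conservatively.
* **Multiple testing**: raw empirical p-values are reported per
  (trait, set) pair; apply `bh_adjust()` across pairs if a
  family-wise view is wanted.

## The per-SNP effects: mixed-model GWAS

Effects come from the single-SNP mixed linear model
$y_i = b_j x_{ij} + g_i + e_i$ with $g \sim N(0, \sigma_a^2 G)$ and
$e \sim N(0, \sigma_e^2 I)$, where $x_{ij} \in \{0,1,2\}$ counts copies
of one allele and $G$ is the VanRaden method-1 genomic relationship
matrix, $G = ZZ'/(2\sum_k p_k(1-p_k))$ with dosages centered by $2p_k$
and missing calls mean-imputed. Phenotypes are assumed pre-adjusted for
fixed environmental effects, so the only fixed effect is the intercept.

Variance components are estimated once by exact REML — the restricted
likelihood is profiled over $\lambda = \sigma_a^2/\sigma_e^2$ on a
41-point log grid spanning $10^{-5}$ to $10^5$ and refined by bounded
scalar optimization in the eigenbasis of $G$, where each evaluation is
$O(n)$ — and then held fixed for every SNP (the EMMAX approximation,
standard in MLM GWAS and accurate when no single SNP explains much
variance). Per-SNP estimates are GLS solves against
$V = \sigma_a^2 G + \sigma_e^2 I$, with Wald p-values from the normal
approximation, appropriate at the intended sample sizes. With
$\sigma_a^2 = 0$ the scan reduces to ordinary least squares exactly,
which the tests assert to $10^{-6}$.

SNP QC precedes the scan: missing-call rate > 0.05, then MAF < 0.01 on
the surviving calls, then exact Hardy–Weinberg p < $10^{-6}$
(Wigginton-style enumeration of heterozygote counts conditional on
allele counts, not the chi-square approximation, for small-count
robustness). The criteria are applied sequentially in that fixed order;
removal counts are order-dependent, so the order is part of the
contract and is reported per filter.

## From expression tables to gene sets

Genes are called differentially expressed at Benjamini–Hochberg
adjusted p < 0.05. DEGs are stratified by direction and by
$|\log_2 \mathrm{FC}|$ into half-open bins $(0,1]$, $(1,2]$, $(2,3]$,
$(3,\infty)$ — `up_fold_01` through `down_fold_3x`. Binning is done on
the $\log_2$ scale: a "fold change 0–1 upregulated" class is
contradictory on the raw scale, while on the $\log_2$ scale all eight
direction × magnitude classes are well defined. Boundary values
($|\log_2\mathrm{FC}|$ exactly 1, 2, 3) fall in the lower bin; the
break points are configurable (`bin_breaks`) since other conventions
exist. A DEG with $\log_2\mathrm{FC}$ exactly 0 has no direction and is
excluded with a message.

Two expression filters are provided with their conventional defaults:
`filter_expressed()` keeps genes with TPM > 0 in at least 7 samples,
and `wgcna_prefilter()` removes genes with TPM < 0.05 in more than one
sample of any one group (the usual pre-filter before co-expression
network construction). Module membership itself is an input — the
package consumes module gene lists, it does not build networks.

## What the simulator emulates — and what it does not

`sim_config()` + `simulate_*()` generate cohorts with planted, fully
known structure so every stage can be verified against ground truth:

* **Landscape**: genes placed on a slot grid (lengths 1–3 kb, ≥ 12 kb
  apart so adjacent 5-kb flank windows cannot merge), SNPs uniform over
  the chromosomes. Default: 150 genes and 2,000 SNPs on two 1.5-Mb
  chromosomes, i.e. one SNP per 1.5 kb so a gene-plus-flanks window
  holds ~8 SNPs.
* **Genotypes**: per-SNP allele frequency uniform on [0.05, 0.5];
  `ld_rho = 0` gives independent Binomial(2, p) dosages, `ld_rho > 0`
  a first-order Markov haplotype process (latent Gaussian AR(1)
  thresholded at the frequency quantile — marginals exact, adjacent
  allelic correlation approximately and slightly below `ld_rho`).
* **Phenotype**: $y = g_c + g_p + e$ with causal effects confined to
  SNPs within 5 kb of the causal set's genes. Components are rescaled
  post hoc so realized variance fractions equal `h2_set` and
  `h2_polygenic` exactly — exact heritability at any $n$, which makes
  parameter-recovery tests sharp. The polygenic background defaults to
  `h2_polygenic = 0.3`, a realistic value for body-composition traits;
  `h2_set = 0` gives a true null in which the "causal" set is just a
  random 15-gene set.
* **DE tables / TPM matrices**: bin memberships assigned by exact
  largest-remainder counts with `padj` consistent with the DEG rule,
  and log-normal TPM with planted silent and low-expression genes.

The simulator does *not* model population structure or family
relatedness beyond the polygenic term, allele-frequency–dependent
effect sizes, long-range LD, or the count nature of RNA-seq. Passing
the validation studies therefore demonstrates the statistical
machinery is correct under its stated assumptions — it does not
certify behaviour on structured real cohorts, where GWAS inflation
(visible in `glance()`'s `lambda_gc`) should be checked as usual.

## Validation studies and the problem sizes used

Three simulation studies, exposed as functions and re-run by both the
test suite and `scripts/acceptance.R`:

* `calibration_study()` — 1,000 independent null cohorts (h2_set = 0;
  500 individuals, 2,000 SNPs, 150 genes, one 15-gene set, 200
  rotations each, full pipeline per cohort). The fraction of empirical
  p ≤ 0.05 should sit near 10/201 ≈ 0.0497, the largest attainable
  grid point below 0.05.
* `power_study()` — 200 cohorts with `h2_set = 0.3` concentrated in
  one 15-gene set among five tested; reports the causal set's
  rejection rate at 0.05 and how often it ranks first.
* `h2_recovery_study()` — 20 cohorts of 1,000 individuals × 2,000
  SNPs at true $h^2 = 0.5$; the mean REML estimate should land within
  ±0.1.

These sizes were chosen so each study finishes in minutes on a single
core while leaving the binomial noise on each reported rate well inside
its acceptance band.

## Numerical notes and limitations

* Eigenvalues of $G$ are clipped at zero (tolerance $10^{-6}$ relative)
  before REML; a matrix failing PSD beyond that is an error.
* The REML profile handles the $\lambda \to 0$ boundary by comparing
  the refined optimum against the grid maximum, so pure-noise
  phenotypes return $\hat h^2 \approx 0$ rather than an interior
  artefact.
* Monomorphic SNPs have undefined effects; they are flagged `skipped`
  (estimate `NA`) rather than silently dropped, and excluded before
  enrichment.
* Chromosome names are opaque strings; `check_chrom_names()` reports
  disjoint naming between files instead of guessing at `chr` prefixes.
* Coordinates are 1-based inclusive internally; BED's 0-based
  half-open records are converted once at the boundary.
* Binary PLINK genotypes are not parsed; positions can be read from
  `.bim`/`.map`, and genotypes travel in a TSV dialect (0/1/2, `NA` or
  −9 missing). Very large panels (hundreds of thousands of SNPs ×
  thousands of individuals) are beyond the in-memory design point of
  this implementation.
```
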