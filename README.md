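# sumenrich

Sum-based enrichment of GWAS signals in gene sets.

## What it is for

Transcriptome studies of a population deliver gene sets — differentially
expressed genes (DEGs) stratified by fold-change bin, or co-expression
modules — while a GWAS on the same animals delivers a per-SNP effect size
for each quantitative trait. `sumenrich` tests whether a gene set is
*enriched* with GWAS signal: whether the SNPs inside its genes (or their
5-kb flanks) carry more association signal than an equally sized,
equally clustered stretch of genome. It is aimed at quantitative and
livestock geneticists integrating expression programs with the genetic
architecture of complex traits.

The pipeline is: SNP quality control → mixed-linear-model GWAS →
gene-set construction from expression tables → sum-based permutation
test, with a synthetic-data module that plants known structure so every
stage is verifiable without external data.

## The statistic

For a gene set with `m_g` SNPs inside member genes or within 5 kb of
them,

```
T_sum = Σ_{i=1..m_g} β_i²
```

where β_i is the per-allele effect from the mixed model
`y = b_j x_j + g + e`, `g ~ N(0, σ²_a G)`, `e ~ N(0, σ²_e I)` (VanRaden
GRM, exact REML variance components, EMMAX-style scan). The null
distribution comes from circular rotation: the SNP membership mask is
rotated by a uniform random offset along the genome-ordered SNP circle,
preserving the set's size and local clustering (hence its LD
footprint), and the one-tailed empirical p-value is
`(1 + #{T_perm ≥ T_obs}) / (n_perm + 1)` with 10,000 rotations by
default.

## Worked example

Simulate a 500-animal cohort in which one 15-gene set carries 30 % of
the phenotypic variance on top of a 30 % polygenic background, run the
GWAS, and test five gene sets:

```r
library(sumenrich)

cfg  <- sim_config(n_individuals = 500, n_snps = 2000, n_genes = 150,
                   n_sets = 5, genes_per_set = 15, h2_set = 0.3,
                   h2_polygenic = 0.3, seed = 42)
land  <- simulate_landscape(cfg)
panel <- simulate_genotypes(land$panel, cfg)
sets  <- simulate_gene_sets(land$annotation, cfg)   # set1 is causal
sim   <- simulate_phenotype(panel, land$annotation, sets, cfg)

scan <- run_gwas(sim$phenotype$y, panel)            # QC + GRM + REML + scan
glance(scan)
#> # A tibble: 1 × 5
#>   n_snps n_skipped sigma_a2 sigma_e2 lambda_gc
#>    <int>     <int>    <dbl>    <dbl>     <dbl>
#> 1   2000         0    0.517    0.541     0.992

gwas <- tidy(scan)[, c("snp_id", "chrom", "pos", "beta", "se", "p")]
res  <- run_enrichment(gwas, land$annotation, sets, n_perm = 10000, seed = 42)
tidy(res)
#> # A tibble: 5 × 8
#>   trait set_name n_genes n_genes_mapped   m_g t_obs n_perm     p_emp
#>   <chr> <chr>      <int>          <int> <int> <dbl>  <int>     <dbl>
#> 1 trait set1          15             15   110 1.75   10000 0.0001000
#> 2 trait set2          15             15   118 0.667  10000 0.929
#> 3 trait set3          15             15   135 0.838  10000 0.805
#> 4 trait set4          15             15   142 1.07   10000 0.305
#> 5 trait set5          15             15   124 0.832  10000 0.617
```

The fitted variance components split the phenotypic variance roughly
in half (ĥ² ≈ 0.49, matching the planted 0.6 total genetic fraction
partly absorbed by the scan), `lambda_gc ≈ 1` shows no inflation, and
only the causal set reaches the smallest attainable p-value,
1/10001 ≈ 1e-4; the null sets sit in the bulk of the null. `autoplot(res)`
draws the per-set −log10 p bar chart, and `write_enrichment_report()`
writes the table with a provenance header.

Gene sets can equally come from expression data:
`bh_adjust()` → `classify_deg_bins()` turns a DE table into the eight
fold-change-bin sets (`up_fold_01` … `down_fold_3x`), and
`read_gene_sets()` loads module membership files. `run_pipeline()`
drives the whole chain from one YAML config and writes a reproducible
manifest.

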