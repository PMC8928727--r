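test_that("landscape simulation is deterministic, respects packing limits", {
  cfg <- sim_config(n_genes = 40, n_snps = 300, seed = 11)
  a <- simulate_landscape(cfg)
  b <- simulate_landscape(cfg)
  expect_identical(a, b)

  expect_gte(min(a$annotation$start), 1)
  expect_true(all(a$annotation$end >= a$annotation$start))
  # genes do not overlap and honor the spacing guarantee per chromosome
  by_chr <- split(a$annotation, a$annotation$chrom)
  for (genes in by_chr) {
    if (nrow(genes) < 2) next
    gaps <- genes$start[-1] - genes$end[-nrow(genes)]
    expect_gte(min(gaps), cfg$min_gene_spacing)
  }

  empty <- simulate_landscape(sim_config(n_genes = 0, n_snps = 100, seed = 1))
  expect_equal(nrow(empty$annotation), 0)
  expect_equal(nrow(empty$panel$map), 100)

  expect_error(
    simulate_landscape(sim_config(n_genes = 500, n_snps = 100,
                                  chrom_lengths = c(chr1 = 100000), seed = 1)),
    "cannot place"
  )
})

test_that("genotype simulation matches its stated frequency and LD behaviour", {
  cfg <- sim_config(n_individuals = 2000, n_snps = 60, n_genes = 10,
                    seed = 21)
  land <- simulate_landscape(cfg)
  panel <- simulate_genotypes(land$panel, cfg)
  expect_identical(panel$geno,
                   simulate_genotypes(land$panel, cfg)$geno) # reproducible

  p_drawn <- attr(panel, "freq")
  p_emp <- colMeans(panel$geno) / 2
  expect_lt(max(abs(p_emp - p_drawn)), 0.05) # binomial bound at n = 2000

  # ld_rho = 0: adjacent dosage correlations are near zero
  r0 <- diag(cor(panel$geno[, -ncol(panel$geno)], panel$geno[, -1]))
  expect_lt(max(abs(r0)), 0.1)

  # positive ld_rho induces substantially larger adjacent correlation
  cfg_ld <- sim_config(n_individuals = 2000, n_snps = 60, n_genes = 10,
                       ld_rho = 0.8, seed = 21)
  panel_ld <- simulate_genotypes(land$panel, cfg_ld)
  r1 <- diag(cor(panel_ld$geno[, -ncol(panel_ld$geno)], panel_ld$geno[, -1]))
  expect_gt(mean(r1), mean(r0) + 0.2)
  # marginal frequencies stay exact under the Markov haplotype process
  expect_lt(max(abs(colMeans(panel_ld$geno) / 2 - attr(panel_ld, "freq"))),
            0.05)
})

test_that("phenotype simulation plants the requested architecture", {
  cfg <- sim_config(n_individuals = 1000, n_snps = 500, n_genes = 60,
                    n_sets = 2, genes_per_set = 10, h2_set = 0.3,
                    h2_polygenic = 0.3, seed = 31)
  land <- simulate_landscape(cfg)
  panel <- simulate_genotypes(land$panel, cfg)
  sets <- simulate_gene_sets(land$annotation, cfg)
  sim <- simulate_phenotype(panel, land$annotation, sets, cfg)

  expect_equal(sim$truth$h2_set_realized, 0.3, tolerance = 0.01)
  expect_equal(sim$truth$h2_polygenic_realized, 0.3, tolerance = 0.01)
  expect_equal(var(sim$phenotype$y), 1, tolerance = 0.05)
  # causal effects confined to the causal-set SNPs
  expect_true(all(sim$truth$causal_beta$snp_id %in%
                    panel$map$snp_id[sim$truth$causal_mask]))
  # regression of y on the true genetic value recovers slope ~ 1
  g <- sim$truth$g_causal + sim$truth$g_polygenic
  slope <- coef(lm(sim$phenotype$y ~ g))[2]
  expect_equal(unname(slope), 1, tolerance = 0.1)

  # null construction: h2_set = 0 leaves no causal component
  cfg0 <- sim_config(n_individuals = 200, n_snps = 200, n_genes = 30,
                     n_sets = 2, genes_per_set = 5, h2_set = 0, seed = 5)
  land0 <- simulate_landscape(cfg0)
  sim0 <- simulate_phenotype(simulate_genotypes(land0$panel, cfg0),
                             land0$annotation,
                             simulate_gene_sets(land0$annotation, cfg0), cfg0)
  expect_true(all(sim0$truth$g_causal == 0))
  expect_equal(nrow(sim0$truth$causal_beta), 0)

  expect_identical(sim$phenotype$y,
                   simulate_phenotype(panel, land$annotation, sets,
                                      cfg)$phenotype$y)
})

test_that("simulated DE tables carry exact bin structure", {
  fr <- c(up_fold_01 = 0.1, up_fold_12 = 0.05, down_fold_3x = 0.05,
          null = 0.8)
  de <- simulate_de_table(200, fr, seed = 7)
  expect_identical(de, simulate_de_table(200, fr, seed = 7))
  expect_equal(unname(table(de$bin_true)[c("up_fold_01", "up_fold_12",
                                           "down_fold_3x", "null")]),
               c(20L, 10L, 10L, 160L), ignore_attr = TRUE)
  expect_true(all(de$padj[de$bin_true != "null"] < 0.05))
  expect_true(all(de$padj[de$bin_true == "null"] >= 0.05))
  expect_true(all(de$pvalue <= de$padj)) # BH can only increase

  expect_error(simulate_de_table(10, c(up_fold_01 = 0.5)), "sum to 1")
  expect_error(simulate_de_table(10, c(sideways = 1)), "unknown bin")

  none <- simulate_de_table(50, c(null = 1), seed = 1)
  expect_equal(sum(none$padj < 0.05), 0)
})

test_that("simulated TPM matrices expose filter targets", {
  sim <- simulate_tpm(100, groups = c(a = 5, b = 5, c = 5), seed = 3)
  expect_equal(ncol(sim$tpm), 16) # gene_id + 15 samples
  expect_named(sim$group_labels)
  expect_true(any(rowSums(as.matrix(sim$tpm[, -1]) > 0) == 0)) # silent genes
})
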