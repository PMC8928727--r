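test_that("exact HWE test matches enumeration-based expectations", {
  # perfect HWE proportions are the modal configuration -> total mass 1
  expect_equal(hwe_test(25, 50, 25), 1)
  # complete heterozygote deficit at p = q = 0.5, n = 100
  expect_lt(hwe_test(50, 0, 50), 1e-6)
  # monomorphic: single attainable configuration
  expect_equal(hwe_test(100, 0, 0), 1)
  expect_error(hwe_test(0, 0, 0), "zero")
})

test_that("exact HWE test agrees with the closed-form oracle", {
  cases <- list(c(25, 50, 25), c(50, 0, 50), c(10, 5, 3), c(1, 10, 40),
                c(0, 3, 7), c(57, 14, 50), c(2, 2, 2))
  for (cs in cases) {
    expect_equal(hwe_test(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]),
                 tolerance = 1e-10,
                 label = paste("counts", paste(cs, collapse = "/")))
  }
})

test_that("QC removes the hand-constructed failures in filter order", {
  panel <- qc_toy_panel()
  res <- qc_filter(panel)
  expect_equal(res$removed, c(missing = 1L, maf = 1L, hwe = 1L))
  expect_equal(nrow(res$panel$map), 7)
  expect_false(any(c("snp_miss", "snp_rare", "snp_hwe") %in%
                     res$panel$map$snp_id))

  # idempotence: filtering a filtered panel removes nothing
  again <- qc_filter(res$panel)
  expect_equal(sum(again$removed), 0)

  # thresholds (0, 1, 0) form the identity filter
  ident <- qc_filter(panel, maf_min = 0, miss_max = 1, hwe_min = 0)
  expect_equal(sum(ident$removed), 0)
  expect_equal(nrow(ident$panel$map), 10)
})

test_that("GRM follows the VanRaden construction", {
  # one SNP, dosages (0, 2), p = 0.5: Z = (-1, 1), denominator 0.5
  p1 <- marker_panel(tibble::tibble(snp_id = "s1", chrom = "1", pos = 100L),
                     matrix(c(0, 2), 2, 1))
  expect_equal(unclass(compute_grm(p1)),
               matrix(c(2, -2, -2, 2), 2), ignore_attr = TRUE)

  cfg <- sim_config(n_individuals = 50, n_snps = 200, n_genes = 0, seed = 9)
  land <- simulate_landscape(cfg)
  panel <- simulate_genotypes(land$panel, cfg)
  G <- compute_grm(panel)
  expect_equal(unclass(G), t(unclass(G)))
  expect_gte(min(eigen(G, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)

  # duplicated individuals: off-diagonal equals the diagonal entry
  dup <- marker_panel(panel$map, panel$geno[c(1, 1, 2:10), ])
  Gd <- compute_grm(dup)
  expect_equal(Gd[1, 2], Gd[1, 1], tolerance = 1e-12)

  # diagonal mean near 1 for many independent SNPs
  cfg2 <- sim_config(n_individuals = 200, n_snps = 5000, n_genes = 0,
                     seed = 10)
  land2 <- simulate_landscape(cfg2)
  G2 <- compute_grm(simulate_genotypes(land2$panel, cfg2))
  expect_gt(mean(diag(G2)), 0.9)
  expect_lt(mean(diag(G2)), 1.1)

  mono <- marker_panel(tibble::tibble(snp_id = "s1", chrom = "1", pos = 1L),
                       matrix(c(2, 2), 2, 1))
  expect_error(compute_grm(mono), "polymorphic")
})

test_that("REML fit is internally consistent and rejects degenerate input", {
  cfg <- sim_config(n_individuals = 300, n_snps = 800, n_genes = 0,
                    h2_polygenic = 0.5, seed = 42)
  land <- simulate_landscape(cfg)
  panel <- simulate_genotypes(land$panel, cfg)
  set.seed(1)
  b <- rnorm(800)
  g <- drop(panel$geno %*% b)
  g <- g / sd(g) * sqrt(0.5)
  e <- rnorm(300)
  y <- g + e / sd(e) * sqrt(0.5)
  fit <- reml_fit(y, compute_grm(panel))
  # restricted log-likelihood at the optimum dominates the whole grid
  expect_gte(fit$log_likelihood, max(fit$grid$loglik) - 1e-8)
  expect_gte(fit$sigma_a2, 0)
  expect_gt(fit$sigma_e2, 0)

  expect_error(reml_fit(rep(1, 300), compute_grm(panel)), "constant")
  expect_error(reml_fit(c(y[-1], NA), compute_grm(panel)), "finite")
})

test_that("null phenotypes on unrelated individuals yield near-zero heritability", {
  h2 <- vapply(1:10, function(i) {
    cfg <- sim_config(n_individuals = 300, n_snps = 1000, n_genes = 0,
                      seed = 100 + i)
    land <- simulate_landscape(cfg)
    panel <- simulate_genotypes(land$panel, cfg)
    set.seed(1000 + i)
    y <- stats::rnorm(300) # pure noise
    reml_fit(y, compute_grm(panel))$h2
  }, 0)
  expect_lte(mean(h2), 0.1)
})

test_that("the scan reduces to OLS when sigma_a2 = 0 and fits exactly when it can", {
  cfg <- sim_config(n_individuals = 80, n_snps = 50, n_genes = 0, seed = 12)
  land <- simulate_landscape(cfg)
  panel <- simulate_genotypes(land$panel, cfg)
  set.seed(2)
  y <- rnorm(80)
  scan <- mlm_scan(y, panel, list(sigma_a2 = 0, sigma_e2 = 1),
                   grm = diag(80))
  ols <- vapply(seq_len(50), function(j) {
    unname(coef(lm(y ~ panel$geno[, j]))[2])
  }, 0)
  expect_equal(scan$beta, ols, tolerance = 1e-6)

  # exact fit: x = (0,1,2), y = (0,1,2), V = I -> slope 1, no residual
  p3 <- marker_panel(tibble::tibble(snp_id = "s", chrom = "1", pos = 1L),
                     matrix(c(0, 1, 2), 3, 1))
  s3 <- mlm_scan(c(0, 1, 2), p3, list(sigma_a2 = 0, sigma_e2 = 1),
                 grm = diag(3))
  expect_equal(s3$beta, 1, tolerance = 1e-10)
})

test_that("with G = I the mixed model equals OLS with inflated residual variance", {
  cfg <- sim_config(n_individuals = 60, n_snps = 40, n_genes = 0, seed = 13)
  land <- simulate_landscape(cfg)
  panel <- simulate_genotypes(land$panel, cfg)
  set.seed(3)
  y <- rnorm(60)
  a <- mlm_scan(y, panel, list(sigma_a2 = 0.4, sigma_e2 = 0.6),
                grm = diag(60))
  b <- mlm_scan(y, panel, list(sigma_a2 = 0, sigma_e2 = 1), grm = diag(60))
  expect_equal(a$beta, b$beta, tolerance = 1e-9)
  expect_equal(a$p, b$p, tolerance = 1e-6)
})

test_that("planted causal SNPs carry larger estimated effects than null SNPs", {
  cfg <- sim_config(n_individuals = 1000, n_snps = 600, n_genes = 60,
                    n_sets = 2, genes_per_set = 15, h2_set = 0.3,
                    h2_polygenic = 0.2, seed = 77)
  land <- simulate_landscape(cfg)
  panel <- simulate_genotypes(land$panel, cfg)
  sets <- simulate_gene_sets(land$annotation, cfg)
  sim <- simulate_phenotype(panel, land$annotation, sets, cfg)
  fit <- reml_fit(sim$phenotype$y, compute_grm(panel))
  scan <- mlm_scan(sim$phenotype$y, panel, fit)
  causal <- sim$truth$causal_mask
  expect_gt(mean(abs(scan$beta[causal])), mean(abs(scan$beta[!causal])))
})

test_that("run_gwas chains QC, GRM, REML and the scan", {
  cfg <- sim_config(n_individuals = 150, n_snps = 300, n_genes = 30,
                    n_sets = 2, genes_per_set = 5, h2_set = 0.2,
                    h2_polygenic = 0.2, seed = 14)
  land <- simulate_landscape(cfg)
  panel <- simulate_genotypes(land$panel, cfg)
  sets <- simulate_gene_sets(land$annotation, cfg)
  sim <- simulate_phenotype(panel, land$annotation, sets, cfg)
  scan <- run_gwas(sim$phenotype$y, panel)
  expect_s3_class(scan, "gwas_scan")
  expect_named(attr(scan, "qc_removed"), c("missing", "maf", "hwe"))
  expect_true(all(scan$p > 0 & scan$p <= 1, na.rm = TRUE))
  gl <- glance(scan)
  expect_equal(gl$n_snps + gl$n_skipped, nrow(scan))
})
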