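test_that("SNP-to-set mapping applies the flank window arithmetic", {
  ann <- toy_annotation(10000, 12000)
  gw <- tibble::tibble(
    snp_id = sprintf("s%d", 1:4), chrom = "chr1",
    pos = c(4999L, 5000L, 12000L, 17001L), beta = 1
  )
  mask <- map_snps_to_set(gw, ann, "g01", flank = 5000)
  expect_equal(as.logical(mask), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(attr(mask, "m_g"), 2)

  # flank 0: gene ends are inclusive
  m0 <- map_snps_to_set(gw, ann, "g01", flank = 0)
  expect_equal(as.logical(m0), c(FALSE, FALSE, TRUE, FALSE))

  # two overlapping genes flag a covered SNP once (boolean mask)
  ann2 <- toy_annotation(c(10000, 11000), c(12000, 13000))
  m2 <- map_snps_to_set(gw, ann2, c("g01", "g02"), flank = 0)
  expect_equal(sum(m2), 1)

  # unknown ids are reported; an entirely unknown set is an error
  expect_message(mu <- map_snps_to_set(gw, ann, c("g01", "nope")),
                 "not in annotation")
  expect_equal(attr(mu, "unmapped"), "nope")
  expect_equal(attr(mu, "n_genes_mapped"), 1)
  expect_error(map_snps_to_set(gw, ann, "nope"), "resolve")
})

test_that("T_sum is the sum of squared effects over the mask", {
  gw <- toy_gwas(c(0.5, -0.5, 1.0))
  expect_equal(t_sum(gw, rep(TRUE, 3)), 1.5)
  expect_equal(t_sum(gw, c(TRUE, TRUE, FALSE)), 0.5)
  expect_equal(t_sum(gw, rep(FALSE, 3)), 0)
  gw$beta[1] <- NA
  expect_error(t_sum(gw, rep(TRUE, 3)), "non-finite")
  expect_error(t_sum(toy_gwas(1), rep(TRUE, 3)), "length")
})

test_that("rotation null matches the exhaustive 4-SNP enumeration", {
  gw <- toy_gwas(c(1, 2, 3, 4))
  mask <- c(TRUE, TRUE, FALSE, FALSE)
  # exhaustive nonzero rotations give T in {13, 25, 17}; observed T = 5
  oracle <- rotation_oracle(gw$beta, mask)
  expect_equal(oracle[1], 5) # offset 0 = observed
  expect_setequal(oracle[-1], c(13, 25, 17))

  perm <- circular_null(gw, mask, n_perm = 500, seed = 4)
  expect_true(all(perm %in% oracle[-1]))
  expect_setequal(unique(perm), c(13, 25, 17))
})

test_that("rotation preserves set size and the closed-form mean identity", {
  set.seed(8)
  beta <- rnorm(40)
  mask <- rep(FALSE, 40)
  mask[c(3:7, 20, 31:33)] <- TRUE
  oracle <- rotation_oracle(beta, mask)
  # each SNP is covered by exactly m_g of the n rotations
  expect_equal(mean(oracle), sum(mask) / 40 * sum(beta^2), tolerance = 1e-12)

  gw <- toy_gwas(beta)
  perm <- circular_null(gw, mask, n_perm = 300, seed = 1)
  expect_true(all(perm %in% oracle[-1]))

  # implied m_g is preserved: with all-equal |beta|, every rotation gives
  # exactly m_g * beta^2
  gw1 <- toy_gwas(rep(0.5, 12))
  p1 <- circular_null(gw1, mask[1:12], n_perm = 50, seed = 2)
  expect_true(all(p1 == sum(mask[1:12]) * 0.25))
})

test_that("sampled rotations converge to uniform over the nonzero offsets", {
  gw <- toy_gwas(c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)[1:10])
  mask <- c(rep(TRUE, 3), rep(FALSE, 7))
  oracle <- rotation_oracle(gw$beta, mask)
  expect_equal(length(unique(oracle)), 10) # distinct stats identify offsets
  perm <- circular_null(gw, mask, n_perm = 9000, seed = 6)
  counts <- table(factor(perm, levels = sort(oracle[-1])))
  gof <- suppressWarnings(chisq.test(counts))
  expect_gt(gof$p.value, 0.01)
})

test_that("per-chromosome rotation keeps masks inside chromosomes", {
  gw <- dplyr::bind_rows(toy_gwas(1:4, chrom = "chr1"),
                         toy_gwas(5:8, chrom = "chr2"))
  gw$snp_id <- sprintf("s%02d", 1:8)
  mask <- c(TRUE, TRUE, rep(FALSE, 6))
  perm <- circular_null(gw, mask, n_perm = 400, seed = 3,
                        per_chromosome = TRUE)
  # mass never leaves chr1: possible stats are sums of 2 adjacent-in-circle
  # chr1 effects
  chr1_oracle <- rotation_oracle(gw$beta[1:4], mask[1:4])
  expect_true(all(perm %in% chr1_oracle[-1]))
})

test_that("empirical p follows the add-one one-tailed rule", {
  expect_equal(empirical_p(10, rep(1, 9)), 0.1)     # greater than all 9
  expect_equal(empirical_p(0, rep(1, 9)), 1)        # at or below all
  expect_equal(empirical_p(5, c(5, rep(1, 18))), 0.1) # tie counts against
  expect_error(empirical_p(1, numeric(0)), "empty")
  # never 0, never above 1
  expect_gte(empirical_p(100, runif(99)), 0.01)
  expect_lte(empirical_p(-1, runif(99)), 1)
})

test_that("scaling up flagged effects never increases the empirical p", {
  set.seed(15)
  for (i in 1:10) {
    beta <- rnorm(30)
    mask <- seq_len(30) %in% sample(30, 6)
    gw <- toy_gwas(beta)
    gw_big <- gw
    gw_big$beta[mask] <- gw_big$beta[mask] * 3
    p1 <- empirical_p(t_sum(gw, mask),
                      circular_null(gw, mask, n_perm = 150, seed = i))
    p2 <- empirical_p(t_sum(gw_big, mask),
                      circular_null(gw_big, mask, n_perm = 150, seed = i))
    expect_lte(p2, p1)
  }
})

test_that("empirical p is uniform on its grid under a rotated true null", {
  set.seed(33)
  beta <- rnorm(200)
  gw <- toy_gwas(beta)
  base <- rep(FALSE, 200)
  base[c(10:19, 101:110)] <- TRUE
  pvals <- vapply(1:1000, function(i) {
    k <- sample(199, 1) # independent rotation assigns a null membership
    mask <- base[(seq_len(200) - 1 - k) %% 200 + 1]
    empirical_p(t_sum(gw, mask),
                circular_null(gw, mask, n_perm = 99, seed = 5000 + i))
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(pvals >= 1 / 100 & pvals <= 1))
})

test_that("run_enrichment reuses masks across traits and is deterministic", {
  cfg <- sim_config(n_individuals = 100, n_snps = 400, n_genes = 40,
                    n_sets = 3, genes_per_set = 8, h2_set = 0.3,
                    h2_polygenic = 0.2, seed = 55)
  land <- simulate_landscape(cfg)
  panel <- simulate_genotypes(land$panel, cfg)
  sets <- simulate_gene_sets(land$annotation, cfg)
  sim <- simulate_phenotype(panel, land$annotation, sets, cfg)
  scan <- run_gwas(sim$phenotype$y, panel, qc = FALSE)
  gw <- scan[!scan$skipped, c("snp_id", "chrom", "pos", "beta", "se", "p")]

  res <- run_enrichment(list(t1 = gw, t2 = gw), land$annotation, sets,
                        n_perm = 100, seed = 21)
  expect_equal(nrow(res), 6)
  # same mask -> identical m_g and t_obs across identical traits
  expect_equal(res$m_g[res$trait == "t1"], res$m_g[res$trait == "t2"])
  expect_equal(res$t_obs[res$trait == "t1"], res$t_obs[res$trait == "t2"])

  res2 <- run_enrichment(list(t1 = gw, t2 = gw), land$annotation, sets,
                         n_perm = 100, seed = 21)
  expect_identical(tidy(res), tidy(res2))

  # misaligned traits are rejected
  gw_bad <- gw[c(2, 1, 3:nrow(gw)), ]
  gw_bad$snp_id <- rev(gw_bad$snp_id)
  expect_error(
    suppressWarnings(run_enrichment(list(a = gw, b = gw_bad),
                                    land$annotation, sets, n_perm = 10)),
    "aligned"
  )

  gl <- glance(res)
  expect_equal(gl$n_tests, 6)
  expect_s3_class(autoplot(res), "ggplot")
})
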