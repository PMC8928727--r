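# Simulation studies used to validate the enrichment test: type-I-error
# calibration under a planted null and power / ranking under planted
# set-level heritability. Each replicate re-runs the whole pipeline
# (landscape, genotypes, phenotype, QC, GRM, REML, scan, enrichment) on a
# fresh dataset.

run_study_replicate <- function(config, n_perm, flank = 5000) {
  land <- simulate_landscape(config)
  panel <- simulate_genotypes(land$panel, config)
  gene_sets <- simulate_gene_sets(land$annotation, config)
  phen <- simulate_phenotype(panel, land$annotation, gene_sets, config,
                             flank = flank)
  qc <- qc_filter(panel)
  grm <- compute_grm(qc$panel)
  fit <- reml_fit(phen$phenotype$y, grm)
  scan <- mlm_scan(phen$phenotype$y, qc$panel, fit)
  gwas <- scan[!scan$skipped, c("snp_id", "chrom", "pos", "beta", "se", "p")]
  res <- run_enrichment(gwas, land$annotation, gene_sets, flank = flank,
                        n_perm = n_perm, seed = config$seed)
  res$h2_hat <- fit$h2
  res
}

#' Type-I-error calibration of the enrichment test
#'
#' Simulates `n_datasets` independent cohorts with no set-level signal
#' (`h2_set = 0`, polygenic background only), runs the full pipeline on
#' each, and records the causal-set empirical p-value. Under a calibrated
#' test the p-values are uniform on their attainable grid, so the
#' fraction at or below any level `alpha` is close to the largest grid
#' point not exceeding `alpha`.
#'
#' @param n_datasets Number of simulated cohorts.
#' @param config A [sim_config()] template; `h2_set` is forced to 0 and
#'   the per-dataset seed is `seed + dataset index`.
#' @param n_perm Permutation replicates per dataset.
#' @param seed Base integer seed.
#' @param .progress Print a dot every 100 datasets.
#' @return A tibble with one row per dataset: `dataset`, `p_emp`, `m_g`,
#'   `t_obs`, `h2_hat`.
#' @export
calibration_study <- function(n_datasets = 1000,
                              config = sim_config(n_individuals = 500,
                                                  n_snps = 2000,
                                                  n_genes = 150,
                                                  n_sets = 1,
                                                  genes_per_set = 15),
                              n_perm = 200, seed = 1L, .progress = FALSE) {
  config$h2_set <- 0
  rows <- vector("list", n_datasets)
  for (i in seq_len(n_datasets)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    res <- run_study_replicate(cfg, n_perm)
    res <- res[res$set_name == config$causal_set_name, ]
    rows[[i]] <- tibble(dataset = i, p_emp = res$p_emp, m_g = res$m_g,
                        t_obs = res$t_obs, h2_hat = res$h2_hat)
    if (.progress && i %% 100 == 0) cat(".")
  }
  if (.progress) cat("\n")
  bind_rows(rows)
}

#' Power and ranking of the enrichment test under planted signal
#'
#' Simulates cohorts in which `h2_set` of the phenotypic variance comes
#' from SNPs inside one causal gene set, tests all `n_sets` sets per
#' cohort, and records the causal set's empirical p-value and its rank
#' among the tested sets (rank 1 = smallest p; ties share the minimum,
#' and a tie for first counts as rank 1 only if the causal set attains
#' the unique minimum).
#'
#' @param n_replicates Number of simulated cohorts.
#' @param config A [sim_config()] template; per-replicate seed is
#'   `seed + replicate index`.
#' @param n_perm Permutation replicates per test.
#' @param seed Base integer seed.
#' @param .progress Print a dot every 50 replicates.
#' @return A tibble with one row per replicate: `replicate`, `p_emp`
#'   (causal set), `rank` (1 = uniquely smallest p among all sets),
#'   `m_g`, `h2_hat`.
#' @export
power_study <- function(n_replicates = 200,
                        config = sim_config(n_individuals = 500,
                                            n_snps = 2000, n_genes = 150,
                                            n_sets = 5, genes_per_set = 15,
                                            h2_set = 0.3),
                        n_perm = 200, seed = 1L, .progress = FALSE) {
  rows <- vector("list", n_replicates)
  for (i in seq_len(n_replicates)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    res <- run_study_replicate(cfg, n_perm)
    causal <- res[res$set_name == config$causal_set_name, ]
    best_other <- min(res$p_emp[res$set_name != config$causal_set_name])
    rows[[i]] <- tibble(
      replicate = i, p_emp = causal$p_emp,
      rank = 1L + sum(res$p_emp[res$set_name != config$causal_set_name] <=
                        causal$p_emp),
      m_g = causal$m_g, h2_hat = causal$h2_hat
    )
    if (.progress && i %% 50 == 0) cat(".")
  }
  if (.progress) cat("\n")
  bind_rows(rows)
}

#' Heritability recovery of the REML fit
#'
#' Simulates purely polygenic phenotypes at a known heritability and
#' refits the variance components, returning one estimate per seed.
#'
#' @param n_seeds Number of independent cohorts.
#' @param config A [sim_config()] template (`h2_polygenic` is the true
#'   heritability; `h2_set` is forced to 0).
#' @param seed Base integer seed.
#' @return A tibble `seed`, `h2_true`, `h2_hat`.
#' @export
h2_recovery_study <- function(n_seeds = 20,
                              config = sim_config(n_individuals = 1000,
                                                  n_snps = 2000,
                                                  n_genes = 0, n_sets = 0,
                                                  h2_polygenic = 0.5),
                              seed = 1L) {
  config$h2_set <- 0
  rows <- vector("list", n_seeds)
  for (i in seq_len(n_seeds)) {
    cfg <- config
    cfg$seed <- as.integer(seed + i)
    land <- simulate_landscape(cfg)
    panel <- simulate_genotypes(land$panel, cfg)
    phen <- with_seed(cfg$seed + 303L, {
      b <- rnorm(nrow(panel$map))
      g <- drop(panel$geno %*% b)
      g <- g / sd(g) * sqrt(cfg$h2_polygenic)
      e <- rnorm(cfg$n_individuals)
      e <- e / sd(e) * sqrt(1 - cfg$h2_polygenic)
      g + e
    })
    fit <- reml_fit(phen, compute_grm(panel))
    rows[[i]] <- tibble(seed = cfg$seed, h2_true = cfg$h2_polygenic,
                        h2_hat = fit$h2)
  }
  bind_rows(rows)
}
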