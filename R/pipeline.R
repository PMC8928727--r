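# End-to-end orchestration from one YAML config: simulate (or load) ->
# QC -> mixed-model GWAS -> gene sets -> enrichment, with a manifest
# capturing seeds, checksums and per-stage row counts.

default_pipeline_config <- function() {
  list(
    seed = 1L,
    simulate = NULL, # sim_config() arguments, or NULL when inputs given
    inputs = NULL,   # paths: markers, phenotype, annotation, gene_sets
    qc = list(maf_min = 0.01, miss_max = 0.05, hwe_min = 1e-6),
    enrich = list(flank = 5000, n_perm = 10000, statistic = "beta",
                  per_chromosome = FALSE)
  )
}

validate_pipeline_config <- function(config) {
  cfg <- modifyList(default_pipeline_config(), config)
  have_sim <- !is.null(cfg$simulate)
  have_inputs <- !is.null(cfg$inputs)
  if (!have_sim && !have_inputs) {
    abort(paste("config must provide either a `simulate` block or an",
                "`inputs` block with markers/phenotype/annotation/gene_sets"))
  }
  if (!have_sim) {
    need <- c("markers", "phenotype", "annotation", "gene_sets")
    missing <- setdiff(need, names(cfg$inputs))
    if (length(missing) > 0) {
      abort(sprintf("inputs block missing: %s", paste(missing, collapse = ", ")))
    }
  }
  for (nm in c("maf_min", "miss_max", "hwe_min")) {
    assert_scalar_number(cfg$qc[[nm]], paste0("qc$", nm), lower = 0)
  }
  assert_scalar_number(cfg$enrich$flank, "enrich$flank", lower = 0)
  assert_scalar_number(cfg$enrich$n_perm, "enrich$n_perm", lower = 1)
  cfg
}

#' Run the full enrichment pipeline from a config
#'
#' Executes simulate (or load) -> SNP QC -> mixed-model GWAS -> enrichment
#' and writes the GWAS summary, gene sets, enrichment report and a run
#' manifest (config snapshot, seed, file checksums, per-stage row counts,
#' package version) into `out_dir`. Re-running with the same config and
#' seed reproduces identical outputs.
#'
#' @param config Path to a YAML file or a config list. Blocks: `seed`;
#'   either `simulate` ([sim_config()] arguments) or `inputs` (paths
#'   `markers`, `phenotype`, `annotation`, `gene_sets`); `qc`
#'   (`maf_min`, `miss_max`, `hwe_min`); `enrich` (`flank`, `n_perm`,
#'   `statistic`, `per_chromosome`).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `results` (the enrichment tibble),
#'   `gwas`, `manifest` and the output paths.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    sim_args$seed <- sim_args$seed %||% cfg$seed
    if (!is.null(sim_args$chrom_lengths)) {
      sim_args$chrom_lengths <- unlist(sim_args$chrom_lengths)
    }
    scfg <- do.call(sim_config, sim_args)
    land <- simulate_landscape(scfg)
    annotation <- land$annotation
    panel <- simulate_genotypes(land$panel, scfg)
    gene_sets <- simulate_gene_sets(annotation, scfg)
    phen <- simulate_phenotype(panel, annotation, gene_sets, scfg,
                               flank = cfg$enrich$flank)
    y <- phen$phenotype$y
  } else {
    panel <- read_marker_panel(cfg$inputs$markers)
    annotation <- read_gene_annotation(cfg$inputs$annotation)
    gene_sets <- read_gene_sets(cfg$inputs$gene_sets)
    ph <- readr::read_tsv(cfg$inputs$phenotype, show_col_types = FALSE,
                          progress = FALSE)
    assert_columns(ph, c("individual_id", "y"), "phenotype file")
    if (is.null(panel$geno)) abort("marker file has no genotype columns")
    ids <- rownames(panel$geno)
    if (!all(ids %in% ph$individual_id)) {
      abort("phenotype file does not cover all genotyped individuals")
    }
    y <- ph$y[match(ids, ph$individual_id)]
    check_chrom_names(panel, annotation)
  }
  counts$individuals <- length(y)
  counts$snps_input <- nrow(panel$map)
  counts$genes <- nrow(annotation)

  qc <- qc_filter(panel, maf_min = cfg$qc$maf_min,
                  miss_max = cfg$qc$miss_max, hwe_min = cfg$qc$hwe_min)
  counts$snps_removed <- as.list(qc$removed)
  counts$snps_after_qc <- nrow(qc$panel$map)

  grm <- compute_grm(qc$panel)
  fit <- reml_fit(y, grm)
  scan <- mlm_scan(y, qc$panel, fit)
  gwas <- scan[!scan$skipped, c("snp_id", "chrom", "pos", "beta", "se", "p")]
  counts$snps_tested <- nrow(gwas)

  results <- run_enrichment(
    gwas, annotation, gene_sets,
    flank = cfg$enrich$flank, n_perm = cfg$enrich$n_perm,
    seed = cfg$seed, statistic = cfg$enrich$statistic %||% "beta",
    per_chromosome = isTRUE(cfg$enrich$per_chromosome)
  )
  counts$enrichment_tests <- nrow(results)

  paths <- list(
    gwas = file.path(out_dir, "gwas.tsv"),
    gene_sets = file.path(out_dir, "gene_sets.tsv"),
    annotation = file.path(out_dir, "annotation.tsv"),
    report = file.path(out_dir, "enrichment.tsv"),
    manifest = file.path(out_dir, "manifest.yaml")
  )
  write_gwas_summary(gwas, paths$gwas)
  write_gene_sets(gene_sets, paths$gene_sets)
  write_gene_annotation(annotation, paths$annotation)
  write_enrichment_report(results, paths$report)

  manifest <- list(
    package_version = as.character(packageVersion("sumenrich")),
    seed = cfg$seed,
    config = cfg,
    variance_components = list(sigma_a2 = fit$sigma_a2,
                               sigma_e2 = fit$sigma_e2, h2 = fit$h2),
    counts = counts,
    checksums = as.list(setNames(
      unname(tools::md5sum(unlist(paths[c("gwas", "gene_sets", "annotation",
                                          "report")]))),
      c("gwas", "gene_sets", "annotation", "report")
    ))
  )
  yaml::write_yaml(manifest, paths$manifest)
  invisible(list(results = results, gwas = gwas, reml = fit,
                 manifest = manifest, paths = paths))
}
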