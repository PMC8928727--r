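# Synthetic genotype / phenotype / expression generator with planted,
# known structure. Every simulate_* function is a pure function of
# (inputs, seed): randomness is drawn under the config seed (plus a fixed
# per-stage offset so stages are independent) and the caller's RNG stream
# is left untouched.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic cohort: panel dimensions, the MAF
#' spectrum, local LD, and the genetic architecture of the phenotype. The
#' phenotype model is `y = X beta_causal + g + e`: causal SNP effects are
#' confined to the genes of `causal_set_name` (within 5-kb flanks) and
#' explain `h2_set` of the phenotypic variance, a polygenic term over all
#' SNPs explains `h2_polygenic`, and the residual takes the remainder.
#'
#' @param n_individuals Number of diploid individuals.
#' @param n_snps Number of SNPs across all chromosomes.
#' @param n_genes Number of non-overlapping genes to place.
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param maf_range Lower/upper bound of the per-SNP minor-allele-frequency
#'   draw, within (0, 0.5].
#' @param ld_rho Adjacent-SNP correlation in (0, 1); 0 gives independent
#'   SNPs. Implemented as a first-order Markov haplotype process.
#' @param n_sets,genes_per_set Number of gene sets to carve out of the
#'   annotation and their size (sets are disjoint).
#' @param causal_set_name Name of the set carrying the causal SNPs.
#' @param h2_set Phenotypic variance fraction explained by causal-set SNPs.
#' @param h2_polygenic Variance fraction of the genome-wide polygenic term.
#' @param gene_length_range Min/max gene length (bp).
#' @param min_gene_spacing Minimum gap between adjacent genes (bp); kept at
#'   12 kb so the 5-kb flank windows of adjacent genes cannot touch.
#' @param seed Integer seed; every simulate_* call is deterministic given it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_individuals = 500,
                       n_snps = 2000,
                       n_genes = 150,
                       chrom_lengths = c(chr1 = 1500000, chr2 = 1500000),
                       maf_range = c(0.05, 0.5),
                       ld_rho = 0,
                       n_sets = 5,
                       genes_per_set = 15,
                       causal_set_name = "set1",
                       h2_set = 0,
                       h2_polygenic = 0.3,
                       gene_length_range = c(1000, 3000),
                       min_gene_spacing = 12000,
                       seed = 1L) {
  assert_scalar_number(n_individuals, "n_individuals", lower = 2)
  assert_scalar_number(n_snps, "n_snps", lower = 2)
  assert_scalar_number(n_genes, "n_genes", lower = 0)
  assert_scalar_number(ld_rho, "ld_rho", lower = 0, upper = 1,
                       upper_strict = TRUE)
  assert_scalar_number(h2_set, "h2_set", lower = 0, upper = 1,
                       upper_strict = TRUE)
  assert_scalar_number(h2_polygenic, "h2_polygenic", lower = 0, upper = 1,
                       upper_strict = TRUE)
  if (h2_set + h2_polygenic >= 1) {
    abort("h2_set + h2_polygenic must be < 1")
  }
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort("maf_range must be (low, high) within (0, 0.5]")
  }
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- sprintf("chr%d", seq_along(chrom_lengths))
  }
  if (any(chrom_lengths < 1)) abort("chrom_lengths must be positive")
  cfg <- list(
    n_individuals = as.integer(n_individuals), n_snps = as.integer(n_snps),
    n_genes = as.integer(n_genes), chrom_lengths = chrom_lengths,
    maf_range = maf_range, ld_rho = ld_rho,
    n_sets = as.integer(n_sets), genes_per_set = as.integer(genes_per_set),
    causal_set_name = causal_set_name, h2_set = h2_set,
    h2_polygenic = h2_polygenic,
    gene_length_range = as.integer(gene_length_range),
    min_gene_spacing = as.integer(min_gene_spacing), seed = as.integer(seed)
  )
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0("<sim_config> n=%d individuals, %d SNPs, %d genes on %d chrom(s)\n",
           "  maf [%.2f, %.2f], ld_rho %.2f; causal set '%s': h2_set %.2f,",
           " h2_polygenic %.2f; seed %d\n"),
    x$n_individuals, x$n_snps, x$n_genes, length(x$chrom_lengths),
    x$maf_range[1], x$maf_range[2], x$ld_rho, x$causal_set_name,
    x$h2_set, x$h2_polygenic, x$seed
  ))
  invisible(x)
}

#' Simulate the gene / SNP genomic landscape
#'
#' Places `n_genes` non-overlapping genes (lengths uniform in
#' `gene_length_range`, adjacent genes at least `min_gene_spacing` apart)
#' and `n_snps` SNP positions uniform over the chromosomes. Genes are
#' placed on a slot grid so the spacing guarantee is exact; an infeasible
#' packing (too many genes for the chromosome lengths) is an error.
#'
#' @param config A [sim_config()].
#' @return A list with `annotation` (gene tibble as from
#'   [read_gene_annotation()]) and `panel` (a [marker_panel()] of positions,
#'   no genotypes yet).
#' @export
simulate_landscape <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed + 101L, {
    lens <- config$chrom_lengths
    slot <- config$min_gene_spacing + max(config$gene_length_range)
    slots_per_chrom <- pmax(0L, as.integer(floor(lens / slot)))
    if (config$n_genes > 0 && sum(slots_per_chrom) < config$n_genes) {
      abort(sprintf(
        "cannot place %d genes with %d bp spacing on %d bp of genome (%d slots)",
        config$n_genes, config$min_gene_spacing, sum(lens),
        sum(slots_per_chrom)
      ))
    }
    annotation <- tibble(gene_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         strand = character())
    if (config$n_genes > 0) {
      n_per_chrom <- apportion(config$n_genes,
                               slots_per_chrom / sum(slots_per_chrom))
      over <- n_per_chrom > slots_per_chrom
      while (any(over)) { # push overflow to chromosomes with room
        spare <- slots_per_chrom - n_per_chrom
        n_per_chrom[over] <- slots_per_chrom[over]
        room <- which(spare > 0)
        need <- config$n_genes - sum(n_per_chrom)
        give <- apportion(need, spare[room] / sum(spare[room]))
        n_per_chrom[room] <- n_per_chrom[room] + give
        over <- n_per_chrom > slots_per_chrom
      }
      pieces <- purrr::map(seq_along(lens), function(ci) {
        k <- n_per_chrom[ci]
        if (k == 0) return(NULL)
        chosen <- sort(sample.int(slots_per_chrom[ci], k))
        len <- sample(seq(config$gene_length_range[1],
                          config$gene_length_range[2]), k, replace = TRUE)
        start <- (chosen - 1L) * slot + 1L
        tibble(chrom = names(lens)[ci], start = start,
               end = start + len - 1L,
               strand = sample(c("+", "-"), k, replace = TRUE))
      })
      annotation <- bind_rows(pieces)
      annotation <- annotation[genome_order(annotation$chrom,
                                            annotation$start), ]
      annotation$gene_id <- sprintf("gene_%04d", seq_len(nrow(annotation)))
      annotation <- annotation[, c("gene_id", "chrom", "start", "end",
                                   "strand")]
    }
    n_snp_per_chrom <- apportion(config$n_snps, lens / sum(lens))
    map <- bind_rows(purrr::map(seq_along(lens), function(ci) {
      k <- n_snp_per_chrom[ci]
      if (k == 0) return(NULL)
      tibble(chrom = names(lens)[ci],
             pos = sort(sample.int(as.integer(lens[ci]), k)))
    }))
    map <- map[genome_order(map$chrom, map$pos), ]
    map$snp_id <- sprintf("snp_%06d", seq_len(nrow(map)))
    list(annotation = annotation,
         panel = marker_panel(map[, c("snp_id", "chrom", "pos")]))
  })
}

#' Simulate diploid genotypes for a marker panel
#'
#' Per-SNP allele frequencies are drawn uniform in `maf_range`. With
#' `ld_rho = 0` dosages are independent Binomial(2, p). With `ld_rho > 0`
#' each haplotype follows a first-order Markov process along each
#' chromosome: a latent Gaussian AR(1) with lag-one correlation `ld_rho`
#' thresholded at the allele-frequency quantile, which keeps the marginal
#' frequencies exact and gives adjacent-SNP allelic correlation close to
#' (slightly below) `ld_rho`. The genotype is the sum of two independent
#' haplotypes.
#'
#' @param panel A [marker_panel()] (positions only is fine).
#' @param config A [sim_config()].
#' @return The panel with a genotype matrix attached; the drawn allele
#'   frequencies are in attribute `"freq"`.
#' @export
simulate_genotypes <- function(panel, config) {
  stopifnot(inherits(panel, "marker_panel"), inherits(config, "sim_config"))
  m <- nrow(panel$map)
  n <- config$n_individuals
  with_seed(config$seed + 202L, {
    p <- runif(m, config$maf_range[1], config$maf_range[2])
    if (config$ld_rho == 0) {
      geno <- matrix(rbinom(n * m, 2L, rep(p, each = n)), nrow = n)
    } else {
      hap <- function() {
        z <- matrix(0, n, m)
        for (chr in unique(panel$map$chrom)) {
          idx <- which(panel$map$chrom == chr)
          z[, idx[1]] <- rnorm(n)
          if (length(idx) > 1) {
            s <- sqrt(1 - config$ld_rho^2)
            for (j in idx[-1]) {
              z[, j] <- config$ld_rho * z[, j - 1] + s * rnorm(n)
            }
          }
        }
        sweep(z, 2, qnorm(p), "<") * 1
      }
      geno <- hap() + hap()
    }
    rownames(geno) <- sprintf("ind_%04d", seq_len(n))
    out <- marker_panel(panel$map, geno)
    attr(out, "freq") <- p
    out
  })
}

#' Simulate a phenotype with planted set-level enrichment
#'
#' Builds `y = g_c + g_p + e`: `g_c` from per-allele effects drawn N(0, 1)
#' on the SNPs mapped to the causal set (gene bodies plus 5-kb flanks),
#' `g_p` from polygenic effects on all SNPs, `e` Gaussian residual. Each
#' component is rescaled post hoc so the realized sample-variance fractions
#' equal `h2_set`, `h2_polygenic` and the remainder exactly. With
#' `h2_set = 0` the causal component is identically zero, giving a true
#' null for the enrichment test.
#'
#' @param panel A [marker_panel()] with genotypes.
#' @param annotation Gene annotation tibble.
#' @param gene_sets Tibble `set_name`, `gene_id` containing
#'   `config$causal_set_name`.
#' @param config A [sim_config()].
#' @param flank Flank (bp) used to map SNPs to the causal set.
#' @return A list with `phenotype` (tibble `individual_id`, `y`) and
#'   `truth` (list: `causal_mask` over panel SNPs, `causal_beta` tibble,
#'   `g_causal`, `g_polygenic`, realized variance fractions).
#' @export
simulate_phenotype <- function(panel, annotation, gene_sets, config,
                               flank = 5000) {
  stopifnot(inherits(panel, "marker_panel"), inherits(config, "sim_config"))
  if (is.null(panel$geno)) abort("panel has no genotypes; run simulate_genotypes()")
  if (!config$causal_set_name %in% gene_sets$set_name) {
    abort(sprintf("causal set '%s' not found in gene_sets",
                  config$causal_set_name))
  }
  causal_genes <- gene_sets$gene_id[gene_sets$set_name ==
                                      config$causal_set_name]
  mask <- map_snps_to_set(panel$map, annotation, causal_genes, flank = flank)
  if (config$h2_set > 0 && sum(mask) == 0) {
    abort(sprintf("causal set '%s' has no SNPs within %d bp of its genes",
                  config$causal_set_name, flank))
  }
  n <- nrow(panel$geno)
  m <- ncol(panel$geno)
  with_seed(config$seed + 303L, {
    scale_to <- function(x, v) {
      if (v == 0) return(rep(0, length(x)))
      sx <- sd(x)
      if (sx == 0) abort("degenerate genetic component (zero variance)")
      x / sx * sqrt(v)
    }
    b_causal <- rep(0, m)
    g_c <- rep(0, n)
    if (config$h2_set > 0) {
      b_causal[mask] <- rnorm(sum(mask))
      g_raw <- drop(panel$geno[, mask, drop = FALSE] %*% b_causal[mask])
      fac <- sqrt(config$h2_set) / sd(g_raw)
      b_causal <- b_causal * fac
      g_c <- g_raw * fac
    }
    b_poly <- rnorm(m)
    g_p <- scale_to(drop(panel$geno %*% b_poly), config$h2_polygenic)
    e <- scale_to(rnorm(n), 1 - config$h2_set - config$h2_polygenic)
    y <- g_c + g_p + e
    list(
      phenotype = tibble(individual_id = rownames(panel$geno), y = y),
      truth = list(
        causal_mask = mask,
        causal_beta = tibble(snp_id = panel$map$snp_id,
                             beta_true = b_causal)[mask & b_causal != 0, ],
        g_causal = g_c, g_polygenic = g_p,
        h2_set_realized = var(g_c) / var(y),
        h2_polygenic_realized = var(g_p) / var(y)
      )
    )
  })
}

#' Carve disjoint gene sets out of an annotation
#'
#' Samples `n_sets` disjoint sets of `genes_per_set` genes each, named
#' `set1` ... `setN`. Used to create one causal set and null comparison
#' sets for calibration and power studies.
#'
#' @param annotation Gene annotation tibble.
#' @param config A [sim_config()] (uses `n_sets`, `genes_per_set`, `seed`).
#' @return A tibble `set_name`, `gene_id`.
#' @export
simulate_gene_sets <- function(annotation, config) {
  stopifnot(inherits(config, "sim_config"))
  need <- config$n_sets * config$genes_per_set
  if (need > nrow(annotation)) {
    abort(sprintf("need %d genes for %d sets but annotation has %d",
                  need, config$n_sets, nrow(annotation)))
  }
  with_seed(config$seed + 404L, {
    picked <- sample(annotation$gene_id, need)
    tibble(
      set_name = rep(sprintf("set%d", seq_len(config$n_sets)),
                     each = config$genes_per_set),
      gene_id = picked
    )
  })
}

# Canonical fold-change bin labels, up/down x |log2fc| in (0,1], (1,2],
# (2,3], (3,Inf).
fold_bin_labels <- function() {
  as.vector(outer(c("up", "down"), c("fold_01", "fold_12", "fold_23", "fold_3x"),
                  paste, sep = "_"))
}

#' Simulate a differential-expression table with known bin labels
#'
#' Assigns genes to the eight (direction, fold-change bin) classes plus a
#' non-DE `null` class by the given fractions (largest-remainder
#' apportionment, so counts are exact). DE genes get `padj` below 0.05 and
#' `|log2fc|` uniform inside their bin; null genes get `padj` at or above
#' 0.05 and small `|log2fc|`. `pvalue` is drawn at or below `padj` so the
#' table is consistent with a Benjamini-Hochberg adjustment.
#'
#' @param n_genes Number of genes, or a character vector of gene ids.
#' @param bin_fractions Named numeric vector over `up_fold_01`,
#'   `up_fold_12`, `up_fold_23`, `up_fold_3x`, `down_fold_01`,
#'   `down_fold_12`, `down_fold_23`, `down_fold_3x`, `null`; must sum to 1
#'   (tolerance 1e-9). Missing names default to 0 (with `null` absorbing
#'   nothing — it must be listed if used).
#' @param seed Integer seed.
#' @return A tibble `gene_id`, `log2fc`, `pvalue`, `padj`, `bin_true`
#'   (the planted label, `"null"` for non-DE genes).
#' @export
simulate_de_table <- function(n_genes, bin_fractions, seed = 1L) {
  gene_ids <- if (is.character(n_genes)) n_genes
              else sprintf("gene_%04d", seq_len(n_genes))
  labels <- c(fold_bin_labels(), "null")
  unknown <- setdiff(names(bin_fractions), labels)
  if (length(unknown) > 0) {
    abort(sprintf("unknown bin label: %s", unknown[1]))
  }
  fr <- setNames(rep(0, length(labels)), labels)
  fr[names(bin_fractions)] <- bin_fractions
  if (abs(sum(fr) - 1) > 1e-9) {
    abort(sprintf("bin_fractions must sum to 1 (got %.12f)", sum(fr)))
  }
  n <- length(gene_ids)
  with_seed(seed + 505L, {
    counts <- apportion(n, fr)
    bins <- rep(labels, counts)[sample.int(n)]
    lims <- list(fold_01 = c(0, 1), fold_12 = c(1, 2), fold_23 = c(2, 3),
                 fold_3x = c(3, 6))
    lfc <- numeric(n)
    padj <- numeric(n)
    for (lab in labels) {
      i <- which(bins == lab)
      if (length(i) == 0) next
      if (lab == "null") {
        lfc[i] <- runif(length(i), -0.5, 0.5)
        padj[i] <- runif(length(i), 0.05, 1)
      } else {
        dir <- if (startsWith(lab, "up")) 1 else -1
        lim <- lims[[sub("^(up|down)_", "", lab)]]
        mag <- lim[1] + (lim[2] - lim[1]) * runif(length(i))
        mag[mag == lim[1]] <- lim[1] + 1e-9 # bins are open below
        lfc[i] <- dir * mag
        padj[i] <- runif(length(i), 1e-8, 0.05 - 1e-8)
      }
    }
    pvalue <- padj * runif(n, 0.2, 1)
    tibble(gene_id = gene_ids, log2fc = lfc, pvalue = pvalue, padj = padj,
           bin_true = bins)
  })
}

#' Simulate a TPM expression matrix
#'
#' Log-normal expression with per-group mean shifts, a configurable
#' fraction of silent (all-zero) genes and a fraction of near-zero
#' low-expression genes, enough structure to exercise the expression
#' filters and the pipeline end to end. Not a model of RNA-seq counts.
#'
#' @param n_genes Number of genes, or a character vector of gene ids.
#' @param groups Named integer vector: samples per group
#'   (e.g. `c(birth = 4, youth = 4, adult = 5)`).
#' @param frac_silent Fraction of genes with TPM 0 everywhere.
#' @param frac_low Fraction of genes with TPM just below 0.05 in two
#'   samples of one group (targets of the co-expression prefilter).
#' @param seed Integer seed.
#' @return A list: `tpm` (tibble, `gene_id` + one column per sample) and
#'   `group_labels` (named character vector, sample -> group).
#' @export
simulate_tpm <- function(n_genes, groups = c(birth = 4, youth = 4, adult = 5),
                         frac_silent = 0.1, frac_low = 0.1, seed = 1L) {
  gene_ids <- if (is.character(n_genes)) n_genes
              else sprintf("gene_%04d", seq_len(n_genes))
  n <- length(gene_ids)
  samples <- unlist(purrr::imap(as.list(groups), function(k, g) {
    sprintf("%s_%d", g, seq_len(k))
  }))
  labels <- setNames(rep(names(groups), groups), samples)
  with_seed(seed + 606L, {
    base <- exp(rnorm(n, 2, 1.5))
    shift <- matrix(exp(rnorm(n * length(groups), 0, 0.5)), n)
    colnames(shift) <- names(groups)
    tpm <- matrix(0, n, length(samples), dimnames = list(NULL, samples))
    for (s in samples) {
      tpm[, s] <- base * shift[, labels[[s]]] * exp(rnorm(n, 0, 0.3))
    }
    silent <- sample.int(n, round(frac_silent * n))
    tpm[silent, ] <- 0
    low <- sample(setdiff(seq_len(n), silent), round(frac_low * n))
    for (i in low) {
      g <- sample(names(groups), 1)
      cols <- sample(names(labels)[labels == g], 2)
      tpm[i, cols] <- runif(2, 0, 0.049)
    }
    list(tpm = dplyr::bind_cols(tibble(gene_id = gene_ids),
                                as_tibble(tpm)),
         group_labels = labels)
  })
}
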