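# The sum-based GWAS-signal enrichment test. For a gene set, the statistic
# is T_sum = sum of squared per-SNP effects over the m_g SNPs falling
# inside the set's gene bodies or their 5-kb flanks. The null rotates the
# membership mask circularly along the genome-ordered SNP vector, which
# preserves both the set size m_g and its local clustering, and the
# one-tailed empirical p-value is (1 + #{T_perm >= T_obs}) / (n_perm + 1).

#' Map SNPs to a gene set with flanking windows
#'
#' Flags every SNP whose position lies within a set gene's body or within
#' `flank` bp up- or downstream of it (symmetric, strand-agnostic; window
#' start clipped at 1). Interval overlap is computed with GenomicRanges.
#'
#' @param gwas A GWAS summary tibble (or a marker map) with `snp_id`,
#'   `chrom`, `pos`, in canonical genome order (re-sorted if not).
#' @param annotation Gene annotation tibble.
#' @param genes Character vector of gene ids, or a gene-set tibble with a
#'   `gene_id` column.
#' @param flank Flank size in bp on each side (default 5000).
#' @return A logical membership mask over the genome-ordered SNPs, with
#'   attributes `m_g` (number of flagged SNPs), `flank`, `n_genes`,
#'   `n_genes_mapped` and `unmapped` (ids absent from the annotation).
#' @examples
#' ann <- tibble::tibble(gene_id = "g1", chrom = "chr1",
#'                       start = 10000, end = 12000, strand = "+")
#' gw <- tibble::tibble(snp_id = c("a", "b"), chrom = "chr1",
#'                      pos = c(4999, 5000), beta = c(1, 1))
#' map_snps_to_set(gw, ann, "g1") # pos 5000 is inside the 5-kb flank
#' @export
map_snps_to_set <- function(gwas, annotation, genes, flank = 5000) {
  if (inherits(gwas, "marker_panel")) gwas <- gwas$map
  assert_columns(gwas, c("snp_id", "chrom", "pos"), "SNP table")
  if (is.data.frame(genes)) genes <- genes$gene_id
  genes <- unique(as.character(genes))
  if (!is_genome_sorted(gwas$chrom, gwas$pos)) {
    warn("SNP table not in genome order; mask computed on sorted order")
    gwas <- gwas[genome_order(gwas$chrom, gwas$pos), ]
  }
  hit <- annotation[annotation$gene_id %in% genes, , drop = FALSE]
  unmapped <- setdiff(genes, hit$gene_id)
  if (nrow(hit) == 0) {
    abort("none of the gene ids resolve against the annotation")
  }
  if (length(unmapped) > 0) {
    inform(sprintf("%d gene id(s) not in annotation (e.g. %s)",
                   length(unmapped), unmapped[1]))
  }
  windows <- GenomicRanges::GRanges(
    hit$chrom,
    IRanges::IRanges(pmax(1, hit$start - flank), hit$end + flank)
  )
  snps <- GenomicRanges::GRanges(gwas$chrom,
                                 IRanges::IRanges(gwas$pos, width = 1))
  mask <- IRanges::overlapsAny(snps, windows)
  structure(mask,
            m_g = sum(mask), flank = flank, n_genes = length(genes),
            n_genes_mapped = length(unique(hit$gene_id)),
            unmapped = unmapped)
}

#' Sum of squared SNP effects over a membership mask
#'
#' `T_sum = sum beta_i^2` over the flagged SNPs; 0 for an empty mask.
#'
#' @param gwas GWAS summary tibble with `beta` (and `se` when
#'   `statistic = "z"`), aligned to the mask.
#' @param mask Logical membership vector of the same length.
#' @param statistic `"beta"` sums squared raw effects (the default);
#'   `"z"` sums squared standardized effects `(beta / se)^2`.
#' @return The non-negative statistic.
#' @export
t_sum <- function(gwas, mask, statistic = c("beta", "z")) {
  statistic <- match.arg(statistic)
  if (length(mask) != nrow(gwas)) {
    abort("mask length must equal the number of SNPs")
  }
  v <- effect_vector(gwas, statistic)
  flagged <- v[mask]
  if (any(!is.finite(flagged))) abort("non-finite effect among flagged SNPs")
  sum(flagged^2)
}

effect_vector <- function(gwas, statistic) {
  if (statistic == "z") {
    assert_columns(gwas, c("beta", "se"), "GWAS summary")
    gwas$beta / gwas$se
  } else {
    assert_columns(gwas, "beta", "GWAS summary")
    gwas$beta
  }
}

# T_sum for every circular offset of idx (0-based offsets), chunked so the
# index matrix stays small.
rotate_sums <- function(beta2, idx0, offsets, n) {
  out <- numeric(length(offsets))
  chunk <- max(1L, as.integer(5e6 / max(length(idx0), 1L)))
  for (s in seq(1L, length(offsets), by = chunk)) {
    e <- min(s + chunk - 1L, length(offsets))
    sh <- outer(idx0, offsets[s:e], "+") %% n + 1L
    out[s:e] <- colSums(matrix(beta2[sh], nrow = length(idx0)))
  }
  out
}

#' Circular-rotation permutation null for T_sum
#'
#' Each replicate draws a rotation offset uniform on `{1, ..., n_snps - 1}`
#' and shifts the whole membership mask by that offset along the
#' genome-ordered SNP circle (chromosomes concatenated in canonical
#' order), leaving the effect vector fixed; the replicate's statistic is
#' the T_sum of the rotated mask. Every rotation preserves `m_g` and the
#' mask's local clustering. Offset 0 (the identity) is excluded; the
#' `+1/(n+1)` empirical-p estimator re-includes the observed statistic
#' conservatively. With `per_chromosome = TRUE` each chromosome's mask
#' segment is rotated independently within the chromosome.
#'
#' @param gwas GWAS summary tibble aligned to the mask.
#' @param mask Logical membership vector.
#' @param n_perm Number of permutation replicates (default 10000).
#' @param seed Optional integer seed for reproducibility.
#' @param statistic `"beta"` or `"z"` (see [t_sum()]).
#' @param per_chromosome Rotate within chromosomes instead of genome-wide.
#' @return Numeric vector of `n_perm` permuted T_sum values.
#' @export
circular_null <- function(gwas, mask, n_perm = 10000, seed = NULL,
                          statistic = c("beta", "z"),
                          per_chromosome = FALSE) {
  statistic <- match.arg(statistic)
  n <- nrow(gwas)
  if (n < 2) abort("need >= 2 SNPs to rotate")
  if (length(mask) != n) abort("mask length must equal the number of SNPs")
  if (n_perm < 1) abort("n_perm must be >= 1")
  v <- effect_vector(gwas, statistic)
  if (any(!is.finite(v))) abort("non-finite effects in GWAS summary")
  beta2 <- v^2
  with_seed(seed, {
    if (!per_chromosome) {
      idx0 <- which(mask) - 1L
      if (length(idx0) == 0) return(rep(0, n_perm))
      offsets <- sample.int(n - 1L, n_perm, replace = TRUE)
      rotate_sums(beta2, idx0, offsets, n)
    } else {
      stats <- rep(0, n_perm)
      for (chr in unique(gwas$chrom)) {
        at <- which(gwas$chrom == chr)
        nc <- length(at)
        idx0 <- which(mask[at]) - 1L
        if (length(idx0) == 0 || nc < 2) {
          stats <- stats + sum(beta2[at][mask[at]])
          next
        }
        offsets <- sample.int(nc - 1L, n_perm, replace = TRUE)
        stats <- stats + rotate_sums(beta2[at], idx0, offsets, nc)
      }
      stats
    }
  })
}

#' One-tailed empirical p-value
#'
#' `p = (1 + #{perm_stats >= t_obs}) / (length(perm_stats) + 1)`. Ties
#' count against significance, and the observed statistic is included in
#' its own null, so `p` is never 0 and lies in
#' `[1 / (n_perm + 1), 1]`.
#'
#' @param t_obs Observed statistic.
#' @param perm_stats Permuted statistics (non-empty).
#' @return The empirical p-value.
#' @export
empirical_p <- function(t_obs, perm_stats) {
  if (length(perm_stats) == 0) abort("perm_stats is empty")
  (1 + sum(perm_stats >= t_obs)) / (length(perm_stats) + 1)
}

#' Gene-set enrichment of GWAS signals
#'
#' For every (trait, gene set) pair: map SNPs to the set with `flank` bp
#' windows, compute `T_sum`, draw the circular-rotation null and report
#' the one-tailed empirical p-value. Masks are computed once per set and
#' reused across traits (all traits must be aligned to the same SNP
#' panel).
#'
#' @param gwas A GWAS summary tibble for one trait, or a named list of
#'   such tibbles (names are trait labels).
#' @param annotation Gene annotation tibble.
#' @param gene_sets Gene-set tibble `set_name`, `gene_id`.
#' @param flank Flank size in bp (default 5000).
#' @param n_perm Permutation replicates per test (default 10000).
#' @param seed Optional integer seed; the whole result is deterministic
#'   given it.
#' @param statistic `"beta"` or `"z"` (see [t_sum()]).
#' @param per_chromosome Rotate within chromosomes (see
#'   [circular_null()]).
#' @param keep_perm Keep each test's permutation distribution as a
#'   list-column `perm_stats`?
#' @return A tibble of class `enrichment`: one row per (trait, set) with
#'   `trait`, `set_name`, `n_genes`, `n_genes_mapped`, `m_g`, `t_obs`,
#'   `n_perm`, `p_emp` (and `perm_stats` when kept).
#' @export
run_enrichment <- function(gwas, annotation, gene_sets, flank = 5000,
                           n_perm = 10000, seed = NULL,
                           statistic = c("beta", "z"),
                           per_chromosome = FALSE, keep_perm = FALSE) {
  statistic <- match.arg(statistic)
  traits <- if (is.data.frame(gwas)) list(trait = gwas) else gwas
  if (is.null(names(traits)) || any(!nzchar(names(traits)))) {
    abort("multi-trait input must be a named list of GWAS summaries")
  }
  assert_columns(gene_sets, c("set_name", "gene_id"), "gene sets")
  ref <- traits[[1]]
  assert_columns(ref, c("snp_id", "chrom", "pos"), "GWAS summary")
  if (!is_genome_sorted(ref$chrom, ref$pos)) {
    warn("GWAS summary not in genome order; re-sorting all traits")
    ord <- genome_order(ref$chrom, ref$pos)
    traits <- purrr::map(traits, ~ .x[ord, , drop = FALSE])
    ref <- traits[[1]]
  }
  for (tr in traits) {
    if (!identical(tr$snp_id, ref$snp_id)) {
      abort("all traits must be aligned to the same SNP panel")
    }
  }
  set_names <- unique(gene_sets$set_name)
  masks <- purrr::map(set_names, function(s) {
    map_snps_to_set(ref, annotation,
                    gene_sets$gene_id[gene_sets$set_name == s], flank = flank)
  })
  names(masks) <- set_names
  rows <- list()
  k <- 0L
  with_seed(seed, {
    for (trait in names(traits)) {
      for (s in set_names) {
        mask <- masks[[s]]
        tobs <- t_sum(traits[[trait]], mask, statistic)
        perm <- circular_null(traits[[trait]], mask, n_perm = n_perm,
                              seed = NULL, statistic = statistic,
                              per_chromosome = per_chromosome)
        k <- k + 1L
        rows[[k]] <- tibble(
          trait = trait, set_name = s,
          n_genes = attr(mask, "n_genes"),
          n_genes_mapped = attr(mask, "n_genes_mapped"),
          m_g = attr(mask, "m_g"),
          t_obs = tobs, n_perm = as.integer(n_perm),
          p_emp = empirical_p(tobs, perm),
          perm_stats = list(perm)
        )
      }
    }
  })
  out <- bind_rows(rows)
  if (!keep_perm) out$perm_stats <- NULL
  class(out) <- c("enrichment", class(out))
  attr(out, "flank") <- flank
  attr(out, "statistic") <- statistic
  attr(out, "null_scheme") <- if (per_chromosome) {
    "circular rotation, per chromosome"
  } else {
    "circular rotation, genome-wide"
  }
  out
}
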