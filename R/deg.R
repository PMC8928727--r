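# Expression filters, BH adjustment, DEG calling and fold-change binning:
# turning DE output tables into the gene-set collections that feed the
# enrichment test.

#' Filter genes by expression breadth
#'
#' Keeps genes with TPM strictly above zero in at least `min_samples`
#' samples — the standard "expressed gene" filter for a small cohort.
#'
#' @param tpm TPM tibble: `gene_id` plus one numeric column per sample.
#' @param min_samples Minimum number of samples with TPM > 0.
#' @return Character vector of expressed gene ids.
#' @export
filter_expressed <- function(tpm, min_samples = 7) {
  assert_columns(tpm, "gene_id", "TPM matrix")
  mat <- as.matrix(tpm[, setdiff(names(tpm), "gene_id")])
  if (ncol(mat) < min_samples) {
    abort(sprintf("TPM matrix has %d samples but min_samples = %d",
                  ncol(mat), min_samples))
  }
  tpm$gene_id[rowSums(mat > 0) >= min_samples]
}

#' Pre-filter genes for co-expression analysis
#'
#' Removes genes with low expression (TPM strictly below `tpm_min`) in
#' more than `max_low_per_group` samples of any one group, the usual
#' pre-filter before building a co-expression network.
#'
#' @param tpm TPM tibble: `gene_id` plus one column per sample.
#' @param group_labels Named character vector mapping every sample column
#'   to its group.
#' @param tpm_min Low-expression threshold (strict `<`).
#' @param max_low_per_group Maximum tolerated low samples per group.
#' @return Character vector of retained gene ids.
#' @export
wgcna_prefilter <- function(tpm, group_labels, tpm_min = 0.05,
                            max_low_per_group = 1) {
  assert_columns(tpm, "gene_id", "TPM matrix")
  samples <- setdiff(names(tpm), "gene_id")
  unknown <- setdiff(samples, names(group_labels))
  if (length(unknown) > 0) {
    abort(sprintf("no group label for sample '%s'", unknown[1]))
  }
  mat <- as.matrix(tpm[, samples])
  low <- mat < tpm_min
  worst <- Reduce(pmax, lapply(unique(group_labels[samples]), function(g) {
    rowSums(low[, samples[group_labels[samples] == g], drop = FALSE])
  }))
  tpm$gene_id[worst <= max_low_per_group]
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement
#' (the standard BH procedure). Input order is preserved.
#'
#' @param pvalues Numeric vector of p-values in (0, 1].
#' @return Adjusted values in (0, 1], same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    abort("pvalues must be in (0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Stratify DEGs into fold-change bins
#'
#' Genes with `padj < padj_max` are differentially expressed; each DEG is
#' assigned to one of eight sets by direction (`up` for positive
#' `log2fc`, `down` for negative) and by `|log2fc|` bin: `fold_01` for
#' (0, 1], `fold_12` for (1, 2], `fold_23` for (2, 3], `fold_3x` for
#' (3, Inf). Boundary values fall in the lower bin. Two combined sets
#' (`up`, `down`) are returned as well. A DEG with `log2fc` exactly 0 has
#' no direction; it is excluded and reported.
#'
#' @param de_table Tibble with `gene_id`, `log2fc` and `padj` (run
#'   [bh_adjust()] first if only raw p-values are available).
#' @param padj_max DEG threshold on the adjusted p-value (strict `<`).
#' @param bin_breaks Right-closed break points on `|log2fc|`; the default
#'   `c(0, 1, 2, 3, Inf)` gives the four canonical bins.
#' @return A gene-set tibble `set_name`, `gene_id` covering the eight
#'   (direction, bin) sets plus `up` and `down`.
#' @export
classify_deg_bins <- function(de_table, padj_max = 0.05,
                              bin_breaks = c(0, 1, 2, 3, Inf)) {
  assert_columns(de_table, c("gene_id", "log2fc"), "DE table")
  if (!"padj" %in% names(de_table)) {
    abort("DE table has no `padj` column; run bh_adjust() on `pvalue` first")
  }
  deg <- de_table[!is.na(de_table$padj) & de_table$padj < padj_max, ]
  zero <- deg$gene_id[deg$log2fc == 0]
  if (length(zero) > 0) {
    inform(sprintf("%d DEG(s) with log2fc == 0 excluded from fold bins",
                   length(zero)))
    deg <- deg[deg$log2fc != 0, ]
  }
  nb <- length(bin_breaks) - 1
  labels <- if (identical(bin_breaks, c(0, 1, 2, 3, Inf))) {
    c("fold_01", "fold_12", "fold_23", "fold_3x")
  } else {
    sprintf("fold_bin%d", seq_len(nb))
  }
  bin <- cut(abs(deg$log2fc), breaks = bin_breaks, labels = labels,
             right = TRUE)
  if (anyNA(bin)) abort("bin_breaks do not cover all |log2fc| values")
  dir <- ifelse(deg$log2fc > 0, "up", "down")
  out <- bind_rows(
    tibble(set_name = paste(dir, as.character(bin), sep = "_"),
           gene_id = deg$gene_id),
    tibble(set_name = dir, gene_id = deg$gene_id)
  )
  attr(out, "zero_log2fc") <- zero
  out
}
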