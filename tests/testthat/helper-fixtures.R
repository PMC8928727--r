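# Fixtures built in code: a hand-constructed QC panel and small builders
# used across test files.

# 10-SNP, 100-individual panel with known QC fates:
#   snp_miss : 6% missing calls            -> fails missingness (> 0.05)
#   snp_rare : one heterozygote (MAF 0.005) -> fails MAF (< 0.01)
#   snp_hwe  : 50/0/50 split                -> fails exact HWE (p < 1e-6)
#   7 clean SNPs in Hardy-Weinberg-ish proportions at MAF 0.3
qc_toy_panel <- function() {
  n <- 100
  clean <- c(rep(0, 49), rep(1, 42), rep(2, 9)) # freq 0.3, near-HWE counts
  geno <- cbind(
    snp_miss = c(rep(NA, 6), clean[7:100]),
    snp_rare = c(1, rep(0, 99)),
    snp_hwe = c(rep(0, 50), rep(2, 50)),
    vapply(1:7, function(i) clean[(seq_len(n) + 13 * i) %% n + 1], numeric(n))
  )
  colnames(geno)[4:10] <- sprintf("snp_clean%d", 1:7)
  map <- tibble::tibble(
    snp_id = colnames(geno), chrom = "chr1",
    pos = as.integer(seq(1000, by = 1000, length.out = 10))
  )
  marker_panel(map, geno)
}

# Tiny GWAS summary on one chromosome with the given effects.
toy_gwas <- function(beta, se = rep(0.1, length(beta)), chrom = "chr1") {
  tibble::tibble(
    snp_id = sprintf("s%02d", seq_along(beta)), chrom = chrom,
    pos = as.integer(seq(100, by = 100, length.out = length(beta))),
    beta = beta, se = se, p = 2 * stats::pnorm(-abs(beta / se))
  )
}

toy_annotation <- function(starts, ends, chrom = "chr1") {
  tibble::tibble(
    gene_id = sprintf("g%02d", seq_along(starts)), chrom = chrom,
    start = as.integer(starts), end = as.integer(ends), strand = "+"
  )
}

# Independent brute-force BH step-up: sort, take p_(i) * n / i, cumulative
# minimum from the largest, cap at 1, unsort.
bh_brute <- function(p) {
  n <- length(p)
  o <- order(p)
  ranked <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(ranked)))
  pmin(adj, 1)[order(o)]
}

# Independent exact-HWE oracle using the closed-form probability of a
# heterozygote count given the allele counts,
#   P(h) = n! / (h1! h! h2!) * 2^h * na! * nb! / (2n)!,
# computed term by term with lchoose/lfactorial and checked to sum to 1
# (no shared code with hwe_test()).
hwe_oracle <- function(n_hom1, n_het, n_hom2) {
  n <- n_hom1 + n_het + n_hom2
  n_a <- 2 * n_hom1 + n_het
  n_b <- 2 * n - n_a
  n_minor <- min(n_a, n_b)
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  prob <- vapply(hets, function(h) {
    h1 <- (n_minor - h) / 2
    h2 <- n - h1 - h
    exp(lfactorial(n) - lfactorial(h1) - lfactorial(h) - lfactorial(h2) +
          h * log(2) + lfactorial(n_minor) + lfactorial(2 * n - n_minor) -
          lfactorial(2 * n))
  }, 0)
  stopifnot(abs(sum(prob) - 1) < 1e-8) # closed form must be normalized
  obs <- prob[hets == n_het]
  sum(prob[prob <= obs * (1 + 1e-10)])
}

# Exhaustive rotation null: T_sum with membership indices shifted by every
# offset 0..n-1 around the SNP circle (offset 0 = observed statistic).
rotation_oracle <- function(beta, mask) {
  n <- length(beta)
  idx <- which(mask)
  vapply(0:(n - 1), function(k) {
    sum(beta[(idx - 1 + k) %% n + 1]^2)
  }, 0)
}
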