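# SNP quality control and the mixed-linear-model association scan.
# Model per SNP j:  y_i = b_j x_ij + g_i + e_i,  g ~ N(0, sigma_a^2 G),
# e ~ N(0, sigma_e^2 I), x in {0,1,2}. Variance components are estimated
# once by REML (EMMAX approximation) and held fixed across SNPs.

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test by enumerating heterozygote counts conditional on
#' the allele counts: the p-value is the total probability of all
#' configurations no more probable than the observed one. This is the
#' small-count-robust exact test PLINK applies during QC.
#'
#' @param n_hom1,n_het,n_hom2 Genotype counts (homozygote, heterozygote,
#'   homozygote).
#' @return The exact two-sided p-value.
#' @examples
#' hwe_test(25, 50, 25) # perfect HWE proportions -> 1
#' hwe_test(50, 0, 50)  # complete heterozygote deficit -> tiny
#' @export
hwe_test <- function(n_hom1, n_het, n_hom2) {
  counts <- c(n_hom1, n_het, n_hom2)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("genotype counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) abort("all genotype counts are zero")
  n_a <- 2 * n_hom1 + n_het # copies of allele 1
  n_minor <- min(n_a, 2 * n - n_a)
  if (n_minor == 0) return(1) # monomorphic: single attainable configuration
  prob <- hwe_het_probs(n, n_minor)
  obs <- prob$p[prob$het == n_het]
  sum(prob$p[prob$p <= obs * (1 + 1e-10)])
}

# Conditional distribution of the heterozygote count given sample size and
# minor allele count. Feasible het counts share the parity of n_minor;
# log P(het = h) is, up to normalization,
#   h log 2 - log(h1! h! h2!)  with h1 = (n_minor - h)/2, h2 = n - h1 - h
# (the hypergeometric-style kernel of the exact HWE test). Cached per
# (n, n_minor) so panel-wide QC does not re-enumerate.
hwe_cache <- new.env(parent = emptyenv())

hwe_het_probs <- function(n, n_minor) {
  key <- paste(n, n_minor)
  hit <- hwe_cache[[key]]
  if (!is.null(hit)) return(hit)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  h1 <- (n_minor - hets) / 2
  h2 <- n - h1 - hets
  logp <- hets * log(2) - lfactorial(h1) - lfactorial(hets) - lfactorial(h2)
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  out <- list(het = hets, p = p)
  if (length(hwe_cache) > 4096) rm(list = ls(hwe_cache), envir = hwe_cache)
  hwe_cache[[key]] <- out
  out
}

# Per-SNP genotype summaries on non-missing calls.
snp_stats <- function(geno) {
  n_called <- colSums(!is.na(geno))
  n_het <- colSums(geno == 1, na.rm = TRUE)
  n_hom2 <- colSums(geno == 2, na.rm = TRUE)
  n_hom0 <- n_called - n_het - n_hom2
  freq <- (2 * n_hom2 + n_het) / (2 * pmax(n_called, 1))
  tibble(
    n_called = n_called,
    miss_rate = 1 - n_called / nrow(geno),
    freq = freq,
    maf = pmin(freq, 1 - freq),
    n_hom0 = n_hom0, n_het = n_het, n_hom2 = n_hom2
  )
}

#' SNP quality control
#'
#' Removes SNPs failing, in order: missing-call rate above `miss_max`,
#' minor allele frequency below `maf_min` (computed on non-missing calls),
#' and exact Hardy-Weinberg p-value below `hwe_min`. The filters run
#' sequentially, so each removal count refers to the panel surviving the
#' previous filter. Defaults are the standard GWAS QC triple
#' (MAF < 0.01, missingness > 0.05, HWE p < 1e-6).
#'
#' @param panel A [marker_panel()] with genotypes.
#' @param maf_min Remove SNPs with MAF strictly below this.
#' @param miss_max Remove SNPs with missing rate strictly above this.
#' @param hwe_min Remove SNPs with exact HWE p strictly below this.
#' @return A list: `panel` (filtered [marker_panel()]) and `removed`
#'   (named integer vector, counts removed by `missing`, `maf`, `hwe`).
#' @export
qc_filter <- function(panel, maf_min = 0.01, miss_max = 0.05,
                      hwe_min = 1e-6) {
  stopifnot(inherits(panel, "marker_panel"))
  if (is.null(panel$geno)) abort("qc_filter() needs genotypes")
  keep_panel <- function(p, keep) {
    structure(list(map = p$map[keep, , drop = FALSE],
                   geno = p$geno[, keep, drop = FALSE]),
              class = "marker_panel")
  }
  removed <- c(missing = 0L, maf = 0L, hwe = 0L)

  st <- snp_stats(panel$geno)
  keep <- st$miss_rate <= miss_max & st$n_called > 0
  removed["missing"] <- sum(!keep)
  panel <- keep_panel(panel, keep)

  st <- snp_stats(panel$geno)
  keep <- st$maf >= maf_min
  removed["maf"] <- sum(!keep)
  panel <- keep_panel(panel, keep)

  st <- snp_stats(panel$geno)
  hwe_p <- purrr::pmap_dbl(list(st$n_hom0, st$n_het, st$n_hom2), hwe_test)
  keep <- hwe_p >= hwe_min
  removed["hwe"] <- sum(!keep)
  panel <- keep_panel(panel, keep)

  if (nrow(panel$map) == 0) warn("no SNPs survive QC")
  list(panel = panel, removed = removed)
}

#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = Z Z' / (2 * sum_k p_k (1 - p_k))` where Z is the dosage matrix
#' centered by twice the allele frequency. Missing dosages are
#' mean-imputed to `2 p_k` before centering (so they contribute zero),
#' making the construction deterministic.
#'
#' @param panel A [marker_panel()] with genotypes.
#' @return An n x n symmetric matrix of class `grm` with attribute
#'   `"denominator"`.
#' @examples
#' p <- marker_panel(tibble::tibble(snp_id = "s1", chrom = "1", pos = 100),
#'                   matrix(c(0, 2), 2, 1))
#' compute_grm(p) # [[2, -2], [-2, 2]]
#' @export
compute_grm <- function(panel) {
  stopifnot(inherits(panel, "marker_panel"))
  geno <- panel$geno
  if (is.null(geno)) abort("compute_grm() needs genotypes")
  if (nrow(geno) < 2) abort("compute_grm() needs >= 2 individuals")
  p <- colMeans(geno, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) abort("no polymorphic SNPs")
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  Z <- sweep(geno[, poly, drop = FALSE], 2, 2 * p[poly])
  Z[is.na(Z)] <- 0 # mean imputation: imputed dosage 2p centers to 0
  G <- tcrossprod(Z) / denom
  structure(G, class = c("grm", "matrix", "array"), denominator = denom)
}

# Restricted log-likelihood of the one-random-effect model, profiled over
# lambda = sigma_a^2 / sigma_e^2, in the eigenbasis of G. Exact (the GLS
# solve is diagonal in this basis). X is the transformed fixed-effect
# design (here the intercept), yt the transformed phenotype, d the
# eigenvalues of G.
reml_loglik <- function(log_lambda, yt, xt, d) {
  lambda <- exp(log_lambda)
  h <- lambda * d + 1
  w <- 1 / h
  xtwx <- sum(w * xt^2)
  bhat <- sum(w * xt * yt) / xtwx
  r <- yt - xt * bhat
  ss <- sum(w * r^2)
  np <- length(yt) - 1
  sigma_e2 <- ss / np
  -0.5 * (np * log(2 * pi * sigma_e2) + np + sum(log(h)) + log(xtwx))
}

#' REML variance components for the one-random-effect model
#'
#' Fits `y = mu + g + e`, `g ~ N(0, sigma_a^2 G)`, `e ~ N(0, sigma_e^2 I)`
#' by restricted maximum likelihood. The restricted likelihood is profiled
#' over the variance ratio `lambda = sigma_a^2 / sigma_e^2` on a log grid
#' spanning 1e-5 to 1e5, then refined by bounded scalar optimization in
#' the eigenbasis of G, where every evaluation is O(n).
#'
#' @param y Numeric phenotype vector (pre-adjusted for fixed effects).
#' @param grm A [compute_grm()] matrix (or any symmetric PSD matrix).
#' @param grid_points Number of log-spaced grid points for the initial
#'   profile.
#' @return An object of class `reml_fit`: list with `sigma_a2`, `sigma_e2`,
#'   `lambda`, `h2` (`sigma_a2 / (sigma_a2 + sigma_e2)`), `log_likelihood`
#'   (restricted), `n`, `grid` (tibble of the profiled grid), and the
#'   eigendecomposition reused by [mlm_scan()].
#' @export
reml_fit <- function(y, grm, grid_points = 41) {
  y <- as.numeric(y)
  if (any(!is.finite(y))) abort("y must be finite")
  n <- length(y)
  if (nrow(grm) != n) abort("length(y) must match nrow(grm)")
  if (var(y) == 0) abort("y is constant; variance components are undefined")
  eg <- eigen(grm, symmetric = TRUE)
  if (min(eg$values) < -1e-6 * max(abs(eg$values))) {
    abort("grm is not positive semidefinite")
  }
  d <- pmax(eg$values, 0)
  yt <- drop(crossprod(eg$vectors, y))
  xt <- drop(crossprod(eg$vectors, rep(1, n)))
  grid <- seq(log(1e-5), log(1e5), length.out = grid_points)
  ll <- vapply(grid, reml_loglik, 0, yt = yt, xt = xt, d = d)
  i <- which.max(ll)
  lo <- grid[max(1, i - 1)]
  hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(reml_loglik, c(lo, hi), maximum = TRUE,
                  yt = yt, xt = xt, d = d, tol = 1e-8)
  # boundary-aware: a flat profile toward lambda -> 0 means sigma_a2 ~ 0
  best_ll <- max(opt$objective, ll[i])
  log_lambda <- if (opt$objective >= ll[i]) opt$maximum else grid[i]
  lambda <- exp(log_lambda)
  h <- lambda * d + 1
  w <- 1 / h
  xtwx <- sum(w * xt^2)
  bhat <- sum(w * xt * yt) / xtwx
  ss <- sum(w * (yt - xt * bhat)^2)
  sigma_e2 <- ss / (n - 1)
  sigma_a2 <- lambda * sigma_e2
  structure(list(
    sigma_a2 = sigma_a2, sigma_e2 = sigma_e2, lambda = lambda,
    h2 = sigma_a2 / (sigma_a2 + sigma_e2),
    log_likelihood = best_ll, n = n,
    grid = tibble(lambda = exp(grid), loglik = ll),
    eigen = list(values = d, vectors = eg$vectors)
  ), class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf(
    "<reml_fit> n = %d: sigma_a2 = %.4g, sigma_e2 = %.4g, h2 = %.3f (logLik %.2f)\n",
    x$n, x$sigma_a2, x$sigma_e2, x$h2, x$log_likelihood
  ))
  invisible(x)
}

#' Mixed-linear-model association scan (EMMAX approximation)
#'
#' Per-SNP generalized least squares with the variance components held
#' fixed: `V = sigma_a^2 G + sigma_e^2 I`, `b_hat_j = (x' V^-1 x)^-1
#' x' V^-1 y` with an intercept, Wald z statistic and normal-approximation
#' p-value. Missing dosages are mean-imputed; monomorphic SNPs (undefined
#' effect) get `NA` estimates and are flagged in the `skipped` column.
#'
#' @param y Phenotype vector, same individuals (and order) as the panel.
#' @param panel A [marker_panel()] with genotypes.
#' @param varcomps A [reml_fit()] on the same `y` and GRM (its cached
#'   eigendecomposition is reused). Alternatively a list with `sigma_a2`,
#'   `sigma_e2` plus a `grm` argument.
#' @param grm Only needed when `varcomps` lacks the cached
#'   eigendecomposition.
#' @return A tibble of class `gwas_scan`: `snp_id`, `chrom`, `pos`,
#'   `beta`, `se`, `z`, `p`, `skipped`.
#' @export
mlm_scan <- function(y, panel, varcomps, grm = NULL) {
  stopifnot(inherits(panel, "marker_panel"))
  geno <- panel$geno
  if (is.null(geno)) abort("mlm_scan() needs genotypes")
  y <- as.numeric(y)
  n <- length(y)
  if (nrow(geno) != n) abort("length(y) must match individuals in panel")
  if (!is.null(varcomps$eigen)) {
    d <- varcomps$eigen$values
    U <- varcomps$eigen$vectors
  } else {
    if (is.null(grm)) abort("supply `grm` when varcomps has no eigendecomposition")
    eg <- eigen(grm, symmetric = TRUE)
    d <- pmax(eg$values, 0)
    U <- eg$vectors
  }
  w <- 1 / (varcomps$sigma_a2 * d + varcomps$sigma_e2)
  X <- geno
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2]]
  }
  yt <- drop(crossprod(U, y))
  ot <- drop(crossprod(U, rep(1, n)))
  Xt <- crossprod(U, X)
  a11 <- sum(w * ot^2)
  b1 <- sum(w * ot * yt)
  a12 <- drop(crossprod(w * ot, Xt))
  a22 <- colSums(w * Xt^2)
  b2 <- drop(crossprod(Xt, w * yt))
  det <- a11 * a22 - a12^2
  # monomorphic after imputation <=> zero dosage variance
  mu <- colMeans(X)
  mono <- unname(colMeans(X^2) - mu^2 < 1e-12)
  det[mono] <- NA
  beta <- unname((a11 * b2 - a12 * b1) / det)
  se <- unname(sqrt(a11 / det))
  z <- beta / se
  p <- pmax(2 * pnorm(-abs(z)), .Machine$double.xmin)
  if (any(mono)) {
    inform(sprintf("%d monomorphic SNP(s) skipped", sum(mono)))
  }
  out <- tibble(
    snp_id = panel$map$snp_id, chrom = panel$map$chrom, pos = panel$map$pos,
    beta = beta, se = se, z = z, p = p, skipped = mono
  )
  class(out) <- c("gwas_scan", class(out))
  attr(out, "varcomps") <- list(sigma_a2 = varcomps$sigma_a2,
                                sigma_e2 = varcomps$sigma_e2)
  out
}

#' Run QC, GRM, REML and the association scan in one call
#'
#' Convenience wrapper chaining [qc_filter()], [compute_grm()],
#' [reml_fit()] and [mlm_scan()]; returns the scan tibble ready for
#' [run_enrichment()] (columns `snp_id`, `chrom`, `pos`, `beta`, `se`, `p`).
#'
#' @param y Phenotype vector.
#' @param panel A [marker_panel()] with genotypes.
#' @param qc Apply [qc_filter()] first (with its defaults)?
#' @return A `gwas_scan` tibble; the QC removal counts, the fitted
#'   variance components and the GRM are in attributes `"qc_removed"`,
#'   `"reml"`.
#' @export
run_gwas <- function(y, panel, qc = TRUE) {
  removed <- c(missing = 0L, maf = 0L, hwe = 0L)
  if (qc) {
    f <- qc_filter(panel)
    panel <- f$panel
    removed <- f$removed
  }
  grm <- compute_grm(panel)
  fit <- reml_fit(y, grm)
  scan <- mlm_scan(y, panel, fit)
  attr(scan, "qc_removed") <- removed
  attr(scan, "reml") <- fit[c("sigma_a2", "sigma_e2", "h2")]
  scan
}
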