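# broom-style tidiers and ggplot2 autoplot methods for the result types.

#' Tidy an enrichment result
#'
#' @param x An `enrichment` tibble from [run_enrichment()].
#' @param ... Unused.
#' @return A plain tibble, one row per (trait, set), without the
#'   permutation list-column.
#' @export
tidy.enrichment <- function(x, ...) {
  out <- as_tibble(x)
  out$perm_stats <- NULL
  out
}

#' Summarise an enrichment run
#'
#' @param x An `enrichment` tibble.
#' @param ... Unused.
#' @return A one-row tibble: number of traits and sets tested, `n_perm`,
#'   flank, statistic, and the smallest empirical p-value.
#' @export
glance.enrichment <- function(x, ...) {
  tibble(
    n_traits = length(unique(x$trait)),
    n_sets = length(unique(x$set_name)),
    n_tests = nrow(x),
    n_perm = x$n_perm[1],
    flank = attr(x, "flank") %||% NA_real_,
    statistic = attr(x, "statistic") %||% "beta",
    min_p_emp = min(x$p_emp)
  )
}

#' Plot enrichment results
#'
#' Bar chart of `-log10(p_emp)` per gene set, faceted by trait, with the
#' 0.05 significance line.
#'
#' @param object An `enrichment` tibble.
#' @param alpha Reference significance level drawn as a dashed line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment <- function(object, alpha = 0.05, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$set_name,
                                   y = -log10(.data$p_emp))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p)[emp]))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Tidy an association scan
#'
#' @param x A `gwas_scan` tibble from [mlm_scan()].
#' @param ... Unused.
#' @return A plain tibble of per-SNP estimates (skipped SNPs dropped).
#' @export
tidy.gwas_scan <- function(x, ...) {
  out <- as_tibble(x)
  out[!out$skipped, setdiff(names(out), "skipped")]
}

#' Summarise an association scan
#'
#' @param x A `gwas_scan` tibble.
#' @param ... Unused.
#' @return One-row tibble: SNPs tested and skipped, the variance
#'   components used, genomic-inflation-style median chi-square ratio.
#' @export
glance.gwas_scan <- function(x, ...) {
  vc <- attr(x, "varcomps") %||% list(sigma_a2 = NA_real_, sigma_e2 = NA_real_)
  z2 <- x$z[!x$skipped]^2
  tibble(
    n_snps = sum(!x$skipped),
    n_skipped = sum(x$skipped),
    sigma_a2 = vc$sigma_a2,
    sigma_e2 = vc$sigma_e2,
    lambda_gc = stats::median(z2) / stats::qchisq(0.5, 1)
  )
}

#' Manhattan-style plot of an association scan
#'
#' @param object A `gwas_scan` tibble.
#' @param ... Unused.
#' @return A ggplot object: `-log10(p)` by position, colored by
#'   chromosome.
#' @export
autoplot.gwas_scan <- function(object, ...) {
  df <- tidy(object)
  df <- df[order(df$chrom, df$pos), ]
  df$index <- seq_len(nrow(df))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = -log10(.data$p),
                                   color = .data$chrom)) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::labs(x = "SNP (genome order)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' Tidy a REML fit
#'
#' @param x A `reml_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per variance component.
#' @export
tidy.reml_fit <- function(x, ...) {
  tibble(term = c("sigma_a2", "sigma_e2"),
         estimate = c(x$sigma_a2, x$sigma_e2))
}

#' Summarise a REML fit
#'
#' @param x A `reml_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `sigma_a2`, `sigma_e2`, `h2`, restricted
#'   log-likelihood, `n`.
#' @export
glance.reml_fit <- function(x, ...) {
  tibble(sigma_a2 = x$sigma_a2, sigma_e2 = x$sigma_e2, h2 = x$h2,
         log_likelihood = x$log_likelihood, n = x$n)
}
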