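# Internal helpers shared across modules.

# Canonical genome order: lexicographic by chromosome name (C locale), then
# ascending position. All per-SNP vectors (effects, membership masks) are
# aligned to this order.
genome_order <- function(chrom, pos) {
  order(chrom, pos, method = "radix")
}

is_genome_sorted <- function(chrom, pos) {
  identical(genome_order(chrom, pos), seq_along(chrom))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "%s is missing mandatory column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 lower_strict = FALSE, upper_strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  lo_ok <- if (lower_strict) x > lower else x >= lower
  hi_ok <- if (upper_strict) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` = %g is outside %s%g, %g%s", name, x,
      if (lower_strict) "(" else "[", lower, upper,
      if (upper_strict) ")" else "]"
    ))
  }
  invisible(x)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# Every simulate_* op routes its randomness through this, which is what makes
# them pure functions of (inputs, seed).
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Largest-remainder apportionment of `n` items to fractions summing to 1.
apportion <- function(n, fractions) {
  raw <- n * fractions
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}
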