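# Readers and writers for every external format the pipeline touches.
# Internal conventions: coordinates 1-based inclusive (BED converted at the
# boundary); chromosome names are opaque strings (no "chr" normalization);
# per-SNP tables are kept in canonical genome order.

#' Read gene annotations from BED, GFF3, or TSV
#'
#' Parses per-gene genomic intervals into the internal 1-based inclusive
#' convention and returns them in deterministic (chromosome, start) order.
#' BED records (0-based, half-open) are converted at the boundary: the BED
#' interval `[s, e)` becomes the 1-based inclusive interval `[s + 1, e]`.
#' From GFF3 only features of type `gene` are kept.
#'
#' @param path Path to the annotation file.
#' @param format One of `"auto"` (by extension), `"bed"`, `"gff3"`, `"tsv"`.
#'   The TSV dialect has a header with columns `gene_id`, `chrom`, `start`,
#'   `end` (1-based inclusive) and optional `strand`.
#' @return A tibble with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand` (one of `"+"`, `"-"`, `"*"` for unknown), sorted by
#'   (`chrom`, `start`).
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t999\t2000\tgeneA", bed)
#' read_gene_annotation(bed)
#' @export
read_gene_annotation <- function(path, format = c("auto", "bed", "gff3", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("annotation file not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      bed = "bed", gff = "gff3", gff3 = "gff3", gtf = "gff3", tsv = "tsv",
      txt = "tsv",
      abort(sprintf("cannot auto-detect annotation format from '%s'", path))
    )
  }
  ann <- switch(format,
    bed = read_annotation_bed(path),
    gff3 = read_annotation_gff3(path),
    tsv = read_annotation_tsv(path)
  )
  validate_gene_annotation(ann)
}

read_annotation_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) abort(sprintf("no BED records in %s", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    abort(sprintf("malformed BED line %d in %s: fewer than 3 columns",
                  which(nf < 3)[1], path))
  }
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(!is.finite(start0) | !is.finite(end0))
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                  bad[1], path))
  }
  bad <- which(end0 <= start0)
  if (length(bad) > 0) {
    abort(sprintf("malformed BED line %d in %s: end <= start", bad[1], path))
  }
  ids <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""),
                sprintf("gene_%05d", seq_along(fields)))
  strand <- ifelse(nf >= 6, vapply(fields, function(f) {
    s <- f[min(6L, length(f))]
    if (s %in% c("+", "-")) s else "*"
  }, ""), "*")
  tibble(
    gene_id = ids,
    chrom = vapply(fields, `[`, "", 1L),
    start = as.integer(start0 + 1), # 0-based half-open -> 1-based inclusive
    end = as.integer(end0),
    strand = strand
  )
}

read_annotation_gff3 <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("GFF3 support requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0) abort(sprintf("no 'gene' features in %s", path))
  meta <- GenomicRanges::mcols(gr)
  ids <- if ("ID" %in% names(meta) && !all(is.na(meta$ID))) {
    as.character(meta$ID)
  } else if ("gene_id" %in% names(meta)) {
    as.character(meta$gene_id)
  } else if ("Name" %in% names(meta)) {
    as.character(meta$Name)
  } else {
    sprintf("gene_%05d", seq_along(gr))
  }
  ids <- sub("^gene:", "", ids)
  strand <- as.character(GenomicRanges::strand(gr))
  tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(strand %in% c("+", "-"), strand, "*")
  )
}

read_annotation_tsv <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(ann, c("gene_id", "chrom", "start", "end"), "annotation TSV")
  if (!"strand" %in% names(ann)) ann$strand <- "*"
  tibble(
    gene_id = as.character(ann$gene_id),
    chrom = as.character(ann$chrom),
    start = as.integer(ann$start),
    end = as.integer(ann$end),
    strand = ifelse(ann$strand %in% c("+", "-"), ann$strand, "*")
  )
}

validate_gene_annotation <- function(ann) {
  if (any(ann$start < 1)) abort("gene annotation: start must be >= 1")
  if (any(ann$end < ann$start)) abort("gene annotation: end < start")
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate gene_id in annotation: %s", dup[1]))
  }
  ann[genome_order(ann$chrom, ann$start), , drop = FALSE]
}

#' Write gene annotations to the TSV dialect
#'
#' @param annotation Tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(annotation, path) {
  assert_columns(annotation, c("gene_id", "chrom", "start", "end"),
                 "annotation")
  if (!"strand" %in% names(annotation)) annotation$strand <- "*"
  readr::write_tsv(annotation[, c("gene_id", "chrom", "start", "end", "strand")],
                   path, progress = FALSE)
  invisible(path)
}

# ---- marker panel -----------------------------------------------------------

#' Construct a marker panel
#'
#' A marker panel holds genome-ordered SNPs (`snp_id`, `chrom`, `pos`, allele
#' codes) and, optionally, a genotype dosage matrix (individuals x SNPs,
#' values 0/1/2/NA counting copies of the alternate allele — genotypes BB,
#' Bb, bb). The panel is always stored in canonical genome order:
#' lexicographic by chromosome name, then ascending position.
#'
#' @param map Tibble with columns `snp_id`, `chrom`, `pos` and optional
#'   `a1`, `a2` allele codes.
#' @param geno Optional numeric matrix, individuals in rows and SNPs in
#'   columns, column order matching `map`. `NA` marks a missing call.
#' @return An object of class `marker_panel`: a list with elements `map`
#'   (tibble, genome-ordered) and `geno` (matrix or `NULL`).
#' @export
marker_panel <- function(map, geno = NULL) {
  assert_columns(map, c("snp_id", "chrom", "pos"), "marker map")
  map <- as_tibble(map)
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  if (!"a1" %in% names(map)) map$a1 <- "A"
  if (!"a2" %in% names(map)) map$a2 <- "B"
  dup <- map$snp_id[duplicated(map$snp_id)]
  if (length(dup) > 0) abort(sprintf("duplicate snp_id: %s", dup[1]))
  if (any(map$pos < 1)) abort("SNP positions must be >= 1")
  if (!is.null(geno)) {
    geno <- as.matrix(geno)
    if (ncol(geno) != nrow(map)) {
      abort(sprintf("genotype matrix has %d columns but map has %d SNPs",
                    ncol(geno), nrow(map)))
    }
    if (!all(is.na(geno) | geno == 0 | geno == 1 | geno == 2)) {
      abort("genotype values must be 0, 1, 2 or missing")
    }
    colnames(geno) <- map$snp_id
    if (is.null(rownames(geno))) {
      rownames(geno) <- sprintf("ind_%04d", seq_len(nrow(geno)))
    }
  }
  ord <- genome_order(map$chrom, map$pos)
  if (!identical(ord, seq_len(nrow(map)))) {
    warn("marker map was not in genome order; re-sorted")
    map <- map[ord, , drop = FALSE]
    if (!is.null(geno)) geno <- geno[, ord, drop = FALSE]
  }
  structure(list(map = map, geno = geno), class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf(
    "<marker_panel> %d SNPs on %d chromosome(s)%s\n",
    nrow(x$map), length(unique(x$map$chrom)),
    if (is.null(x$geno)) ", no genotypes"
    else sprintf(", genotypes for %d individuals", nrow(x$geno))
  ))
  print(head(x$map, 5))
  invisible(x)
}

#' @export
dim.marker_panel <- function(x) {
  c(if (is.null(x$geno)) 0L else nrow(x$geno), nrow(x$map))
}

#' Read a marker panel from a TSV dialect or PLINK text map
#'
#' The TSV dialect has a header row `snp_id`, `chrom`, `pos` followed by one
#' genotype column per individual, values in \{0, 1, 2\} with `NA` or `-9`
#' for missing calls. PLINK `.map`/`.bim` files supply positions only (no
#' genotypes). Input not in genome order is re-sorted with a warning.
#'
#' @param path Path to the marker file.
#' @param format `"auto"`, `"tsv"`, or `"plink_map"` (.map/.bim).
#' @return A [marker_panel()].
#' @export
read_marker_panel <- function(path, format = c("auto", "tsv", "plink_map")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("marker file not found: %s", path))
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
      map = "plink_map", bim = "plink_map", "tsv")
  }
  if (format == "plink_map") {
    raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    if (ncol(raw) < 4) abort(sprintf("%s: expected >= 4 columns", path))
    # .map: chrom, id, cm, pos ; .bim adds a1, a2
    map <- tibble(
      snp_id = as.character(raw[[2]]),
      chrom = as.character(raw[[1]]),
      pos = as.integer(raw[[4]])
    )
    if (ncol(raw) >= 6) {
      map$a1 <- as.character(raw[[5]])
      map$a2 <- as.character(raw[[6]])
    }
    return(marker_panel(map))
  }
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(raw, c("snp_id", "chrom", "pos"), "marker TSV")
  meta_cols <- intersect(c("snp_id", "chrom", "pos", "a1", "a2"), names(raw))
  ind_cols <- setdiff(names(raw), meta_cols)
  geno <- NULL
  if (length(ind_cols) > 0) {
    geno <- t(as.matrix(raw[, ind_cols]))
    mode(geno) <- "numeric"
    geno[geno == -9] <- NA # PLINK-compatible missing code
    rownames(geno) <- ind_cols
  }
  marker_panel(raw[, meta_cols], geno)
}

#' Write a marker panel to the TSV dialect
#'
#' @param panel A [marker_panel()].
#' @param path Output path.
#' @param missing_code Value written for missing genotypes (`"NA"` or `-9`).
#' @return `path`, invisibly.
#' @export
write_marker_panel <- function(panel, path, missing_code = "NA") {
  stopifnot(inherits(panel, "marker_panel"))
  out <- panel$map[, c("snp_id", "chrom", "pos", "a1", "a2")]
  if (!is.null(panel$geno)) {
    g <- t(panel$geno)
    out <- dplyr::bind_cols(out, as_tibble(g, .name_repair = "minimal"))
  }
  readr::write_tsv(out, path, na = as.character(missing_code), progress = FALSE)
  invisible(path)
}

# ---- GWAS summary -----------------------------------------------------------

#' Read GWAS summary statistics
#'
#' Mandatory columns `snp_id`, `chrom`, `pos`, `beta` (per-allele effect);
#' optional `se` and `p`. Rows are returned in canonical genome order.
#'
#' @param path Path to a TSV file.
#' @return A tibble `snp_id`, `chrom`, `pos`, `beta` (+ `se`, `p` when
#'   present), genome-ordered.
#' @export
read_gwas_summary <- function(path) {
  if (!file.exists(path)) abort(sprintf("GWAS summary file not found: %s", path))
  gs <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                        comment = "#")
  assert_columns(gs, c("snp_id", "chrom", "pos", "beta"), "GWAS summary")
  gs$snp_id <- as.character(gs$snp_id)
  gs$chrom <- as.character(gs$chrom)
  gs$pos <- as.integer(gs$pos)
  validate_gwas_summary(as_tibble(gs))
}

validate_gwas_summary <- function(gs) {
  dup <- gs$snp_id[duplicated(gs$snp_id)]
  if (length(dup) > 0) abort(sprintf("duplicate snp_id in GWAS summary: %s", dup[1]))
  if ("se" %in% names(gs) && any(!is.na(gs$se) & gs$se <= 0)) {
    abort("GWAS summary: se must be > 0")
  }
  if ("p" %in% names(gs) && any(!is.na(gs$p) & (gs$p <= 0 | gs$p > 1))) {
    abort("GWAS summary: p must be in (0, 1]")
  }
  gs[genome_order(gs$chrom, gs$pos), , drop = FALSE]
}

#' Write GWAS summary statistics
#' @param gwas GWAS summary tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gwas_summary <- function(gwas, path) {
  assert_columns(gwas, c("snp_id", "chrom", "pos", "beta"), "GWAS summary")
  readr::write_tsv(gwas, path, progress = FALSE)
  invisible(path)
}

# ---- gene sets --------------------------------------------------------------

#' Read a gene-set collection
#'
#' Long format: one row per (set, gene), header `set_name`, `gene_id`.
#' Sets may overlap. Gene ids that do not resolve against an annotation are
#' reported by [map_snps_to_set()], not here.
#'
#' @param path Path to a TSV file.
#' @return A tibble `set_name`, `gene_id` with duplicates removed.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort(sprintf("gene-set file not found: %s", path))
  gsets <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(gsets, c("set_name", "gene_id"), "gene-set file")
  distinct(tibble(set_name = as.character(gsets$set_name),
                  gene_id = as.character(gsets$gene_id)))
}

#' Write a gene-set collection
#' @param gene_sets Tibble `set_name`, `gene_id`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(gene_sets, path) {
  assert_columns(gene_sets, c("set_name", "gene_id"), "gene sets")
  readr::write_tsv(gene_sets[, c("set_name", "gene_id")], path,
                   progress = FALSE)
  invisible(path)
}

# ---- DE table ---------------------------------------------------------------

#' Read a differential-expression table
#'
#' Mandatory columns `gene_id`, `log2fc`, `pvalue`; optional `padj`
#' (Benjamini-Hochberg adjusted). One row per gene.
#'
#' @param path Path to a TSV file.
#' @return A tibble `gene_id`, `log2fc`, `pvalue` (+ `padj` when present).
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("DE table not found: %s", path))
  de <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(de, c("gene_id", "log2fc", "pvalue"), "DE table")
  dup <- de$gene_id[duplicated(de$gene_id)]
  if (length(dup) > 0) abort(sprintf("duplicate gene_id in DE table: %s", dup[1]))
  for (col in intersect(c("pvalue", "padj"), names(de))) {
    v <- de[[col]]
    if (any(!is.na(v) & (v <= 0 | v > 1))) {
      abort(sprintf("DE table: %s must be in (0, 1]", col))
    }
  }
  as_tibble(de)
}

#' Write a differential-expression table
#' @param de_table Tibble `gene_id`, `log2fc`, `pvalue`\[, `padj`\].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de_table, path) {
  assert_columns(de_table, c("gene_id", "log2fc", "pvalue"), "DE table")
  readr::write_tsv(de_table, path, progress = FALSE)
  invisible(path)
}

# ---- TPM matrix -------------------------------------------------------------

#' Read a TPM expression matrix
#'
#' TSV with a `gene_id` column followed by one numeric column per sample.
#'
#' @param path Path to a TSV file.
#' @return A tibble, `gene_id` first.
#' @export
read_tpm_matrix <- function(path) {
  if (!file.exists(path)) abort(sprintf("TPM matrix not found: %s", path))
  tpm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_columns(tpm, "gene_id", "TPM matrix")
  if (ncol(tpm) < 2) abort("TPM matrix has no sample columns")
  as_tibble(tpm)
}

#' Write a TPM expression matrix
#' @param tpm Tibble with `gene_id` plus one column per sample.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tpm_matrix <- function(tpm, path) {
  assert_columns(tpm, "gene_id", "TPM matrix")
  readr::write_tsv(tpm, path, progress = FALSE)
  invisible(path)
}

# ---- enrichment report ------------------------------------------------------

#' Write an enrichment report
#'
#' One row per (trait, set): `trait`, `set_name`, `n_genes`,
#' `n_genes_mapped`, `m_g`, `t_obs`, `n_perm`, `p_emp`. Provenance
#' (package version, flank, null scheme) is recorded in `#`-prefixed header
#' lines.
#'
#' @param results An enrichment result tibble from [run_enrichment()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_enrichment_report <- function(results, path) {
  cols <- c("trait", "set_name", "n_genes", "n_genes_mapped", "m_g",
            "t_obs", "n_perm", "p_emp")
  assert_columns(results, cols, "enrichment results")
  hdr <- c(
    sprintf("# sumenrich %s", as.character(packageVersion("sumenrich"))),
    sprintf("# flank_bp: %s", attr(results, "flank") %||% "NA"),
    sprintf("# null: %s", attr(results, "null_scheme") %||% "circular rotation, genome-wide"),
    sprintf("# statistic: %s", attr(results, "statistic") %||% "beta"),
    "# grm: VanRaden method 1, all SNPs, no LOCO"
  )
  writeLines(hdr, path)
  readr::write_tsv(as_tibble(results)[, cols], path, append = TRUE,
                   col_names = TRUE, progress = FALSE)
  invisible(path)
}

#' Read back an enrichment report
#' @param path Path written by [write_enrichment_report()].
#' @return A tibble with the report columns.
#' @export
read_enrichment_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("report not found: %s", path))
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Report chromosome-name disjointness between two inputs
#'
#' Chromosome names are opaque strings; a `"chr1"` vs `"1"` mismatch between
#' files silently maps nothing. This check makes such mismatches loud.
#'
#' @param a,b Data frames with a `chrom` column (or a [marker_panel()]).
#' @return A list with elements `shared`, `only_a`, `only_b` (character
#'   vectors of chromosome names). Warns when no names are shared.
#' @export
check_chrom_names <- function(a, b) {
  ca <- unique(if (inherits(a, "marker_panel")) a$map$chrom else a$chrom)
  cb <- unique(if (inherits(b, "marker_panel")) b$map$chrom else b$chrom)
  res <- list(shared = intersect(ca, cb), only_a = setdiff(ca, cb),
              only_b = setdiff(cb, ca))
  if (length(res$shared) == 0) {
    warn(sprintf("no shared chromosome names (e.g. '%s' vs '%s')",
                 ca[1], cb[1]))
  }
  res
}
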