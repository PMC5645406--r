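#' Read a pool design table
#'
#' A pool design describes the pooled-sequencing layout: one row per
#' pool with its case/control label and the number of individuals pooled
#' (default 16 per pool, with 37 case and 35 control pools).
#' `alleles` is derived as `2 * n_individuals`.
#'
#' @param path TSV with columns `pool_id`, `label`, `n_individuals`.
#' @return Tibble `pool_id`, `label`, `n_individuals`, `alleles`.
#' @export
read_pool_design <- function(path) {
  if (!file.exists(path)) abort_config(paste0("no such file: ", path))
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("pool_id", "label", "n_individuals")
  if (!all(need %in% names(d))) {
    abort_config(paste0("pool design needs columns: ", paste(need, collapse = ", ")))
  }
  validate_pool_design(tibble(
    pool_id = as.character(d$pool_id),
    label = as.character(d$label),
    n_individuals = as.integer(d$n_individuals),
    alleles = 2L * as.integer(d$n_individuals)
  ))
}

validate_pool_design <- function(design) {
  if (anyDuplicated(design$pool_id)) abort_data("duplicate pool_id in pool design")
  if (!all(design$label %in% c("case", "control"))) {
    abort_data("pool labels must be 'case' or 'control'")
  }
  if (any(design$n_individuals < 1)) abort_data("n_individuals must be positive")
  design
}

#' Build a pool design in code
#'
#' @param n_case,n_control Number of case and control pools.
#' @param pool_size Individuals per pool.
#' @return Pool design tibble as from [read_pool_design()].
#' @export
pool_design <- function(n_case = 37, n_control = 35, pool_size = 16) {
  validate_pool_design(tibble(
    pool_id = c(sprintf("case_%02d", seq_len(n_case)),
                sprintf("ctrl_%02d", seq_len(n_control))),
    label = rep(c("case", "control"), c(n_case, n_control)),
    n_individuals = as.integer(pool_size),
    alleles = 2L * as.integer(pool_size)
  ))
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Validate a pooled variant table
#'
#' Checks the invariants of the pooled representation: one column of
#' non-reference allele rates per pool, every rate in \[0, 1\], and a
#' unique `(chrom, pos, ref, alt)` key per row.
#'
#' @param variants Variant tibble.
#' @param design Pool design tibble.
#' @return The validated tibble, invisibly coerced to a tibble.
#' @export
validate_variants <- function(variants, design) {
  v <- as_tibble(variants)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(v))) {
    abort_config(paste0("variant table needs columns: ", paste(need, collapse = ", ")))
  }
  missing_pools <- setdiff(design$pool_id, names(v))
  if (length(missing_pools) > 0) {
    abort_config(paste0("variant table lacks pool columns: ",
                        paste(head(missing_pools, 5), collapse = ", ")))
  }
  for (p in design$pool_id) {
    r <- v[[p]]
    if (!is.numeric(r)) abort_data(paste0("pool column not numeric: ", p))
    bad <- which(is.na(r) | r < 0 | r > 1)
    if (length(bad) > 0) {
      abort_data(sprintf("rate outside [0,1] at %s:%d (pool %s)",
                         v$chrom[bad[1]], v$pos[bad[1]], p))
    }
  }
  dup <- which(duplicated(variant_key(v)))
  if (length(dup) > 0) {
    abort_data(sprintf("duplicate variant record %s:%d %s>%s",
                       v$chrom[dup[1]], v$pos[dup[1]], v$ref[dup[1]], v$alt[dup[1]]))
  }
  v
}

#' Read a pooled variant table
#'
#' The native dialect is TSV with fixed columns `chrom`, `pos`, `ref`,
#' `alt`, one numeric column of non-reference allele rates per pool in
#' the design, and any optional annotation columns (`is_coding`,
#' `is_synonymous`, `gerp`, `in_dhs`, `ref_panel_af`, `low_confidence`,
#' `gene_id`, ...), which are carried through unchanged.
#'
#' @param path TSV path.
#' @param design Pool design (see [read_pool_design()]); every
#'   `pool_id` must appear as a column.
#' @return Validated variant tibble.
#' @export
read_variant_table <- function(path, design) {
  if (!file.exists(path)) abort_config(paste0("no such file: ", path))
  v <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("pos" %in% names(v)) v$pos <- as.integer(v$pos)
  validate_variants(v, design)
}

#' Read pooled variant rates from a VCF
#'
#' Pulls one allele-rate per pool from a per-sample FORMAT field (the
#' pools are the VCF samples). Multi-allelic records must be decomposed
#' upstream; rows whose ALT contains a comma are rejected.
#'
#' @param path VCF path (plain text or bgzipped).
#' @param design Pool design; sample names must match `pool_id`s.
#' @param format_field FORMAT key holding the per-pool allele rate.
#' @return Validated variant tibble in the native wide layout.
#' @export
read_variant_vcf <- function(path, design, format_field = "AF") {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort_config("VCF input requires the vcfR package")
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (any(grepl(",", fix$ALT, fixed = TRUE))) {
    abort_data("multi-allelic VCF records must be decomposed upstream")
  }
  af <- vcfR::extract.gt(vcf, element = format_field, as.numeric = TRUE)
  v <- tibble(chrom = fix$CHROM, pos = as.integer(fix$POS),
              ref = fix$REF, alt = fix$ALT)
  for (p in colnames(af)) v[[p]] <- unname(af[, p])
  validate_variants(v, design)
}

#' Read a reference-cohort allele-frequency table
#'
#' @param path TSV with columns `chrom`, `pos`, `ref`, `alt`, `af`.
#' @param name Cohort name (informational).
#' @param n_individuals Cohort size; sets the allele-frequency floor
#'   `1 / (2 * n_individuals)` used for variants absent from the table.
#' @return A `reference_cohort` object (list with `name`,
#'   `n_individuals`, and the `af` tibble).
#' @export
read_reference_cohort <- function(path, name = "reference", n_individuals) {
  if (!file.exists(path)) abort_config(paste0("no such file: ", path))
  af <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "af")
  if (!all(need %in% names(af))) {
    abort_config(paste0("reference table needs columns: ", paste(need, collapse = ", ")))
  }
  af$pos <- as.integer(af$pos)
  reference_cohort(af[need], name = name, n_individuals = n_individuals)
}

#' Construct a reference cohort object
#'
#' @param af Tibble `chrom, pos, ref, alt, af`.
#' @param name Cohort name.
#' @param n_individuals Positive integer cohort size.
#' @return A `reference_cohort` object.
#' @export
reference_cohort <- function(af, name = "reference", n_individuals) {
  if (n_individuals <= 0) abort_data("reference n_individuals must be positive")
  af <- as_tibble(af)
  if (any(af$af < 0 | af$af > 1)) abort_data("reference AF outside [0, 1]")
  structure(list(name = name, n_individuals = as.integer(n_individuals), af = af),
            class = "reference_cohort")
}

#' @method print reference_cohort
#' @export
print.reference_cohort <- function(x, ...) {
  cat(sprintf("<reference_cohort '%s': %d individuals, %d sites>\n",
              x$name, x$n_individuals, nrow(x$af)))
  invisible(x)
}

#' Read gene sets in GMT format
#'
#' One set per line: set id, description, then member gene symbols, all
#' tab-separated.
#'
#' @param path GMT path.
#' @return Tibble with `set_id`, `name`, and list-column `genes`
#'   (unique, non-empty member vectors).
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) abort_config(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(parts, length, 1L) < 3)
  if (length(bad) > 0) abort_data(sprintf("GMT line %d has no members", bad[1]))
  tibble(
    set_id = vapply(parts, `[[`, "", 1),
    name = vapply(parts, `[[`, "", 2),
    genes = lapply(parts, function(x) unique(x[-(1:2)]))
  )
}

#' Read gene models (per-isoform exons)
#'
#' BED-derived layout: one exon per row with 0-based half-open
#' coordinates and `gene_id` / `isoform_id` columns. Exons within an
#' isoform must be sorted and non-overlapping.
#'
#' @param path TSV with columns `chrom`, `start`, `end`, `gene_id`,
#'   `isoform_id`.
#' @return Validated tibble of exon intervals.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) abort_config(paste0("no such file: ", path))
  gm <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end", "gene_id", "isoform_id")
  if (!all(need %in% names(gm))) {
    abort_config(paste0("gene model needs columns: ", paste(need, collapse = ", ")))
  }
  gm$start <- as.integer(gm$start)
  gm$end <- as.integer(gm$end)
  validate_gene_models(as_tibble(gm))
}

validate_gene_models <- function(gm) {
  validate_intervals(gm)
  split_iso <- split(gm, paste(gm$gene_id, gm$isoform_id, sep = "\r"))
  for (iso in split_iso) {
    o <- order(iso$start)
    if (any(iso$start[o][-1] < iso$end[o][-length(o)])) {
      abort_data(sprintf("overlapping exons in isoform %s of %s",
                         iso$isoform_id[1], iso$gene_id[1]))
    }
  }
  gm
}

# p-values leave as scientific strings with full precision so that the
# write/read pair is an exact round trip.
fmt_p <- function(p) ifelse(is.na(p), "NA", sprintf("%.16e", p))

#' Write a results table
#'
#' Deterministic column order; p-value columns (any column whose name
#' starts with `p_`) are serialized in scientific notation at full
#' double precision so `read_results(write_results(x)) == x`.
#'
#' @param results Result tibble (e.g. from [run_polystrat()]).
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  out <- as_tibble(results)
  for (col in grep("^p_", names(out), value = TRUE)) {
    out[[col]] <- fmt_p(out[[col]])
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read back a results table written by [write_results()]
#'
#' @param path TSV path.
#' @return Tibble with p-value columns parsed back to numeric.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) abort_config(paste0("no such file: ", path))
  res <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  for (col in grep("^p_", names(res), value = TRUE)) {
    res[[col]] <- as.numeric(res[[col]])
  }
  res
}
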