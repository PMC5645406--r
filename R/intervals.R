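#' Read a BED interval file
#'
#' BED is 0-based half-open: a line `chr1 99 100` covers the single
#' 1-based position 100. Columns beyond the fourth are ignored; the
#' fourth, when present, is kept as `name` (used for gene-target and
#' exon tracks).
#'
#' @param path Path to a BED file (no header).
#' @return Tibble with `chrom`, `start`, `end` and optionally `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort_config(paste0("no such file: ", path))
  raw <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                         progress = FALSE, comment = "#")
  if (ncol(raw) < 3) abort_data("BED file needs at least 3 columns")
  bed <- tibble(
    chrom = as.character(raw[[1]]),
    start = as.integer(raw[[2]]),
    end = as.integer(raw[[3]])
  )
  if (ncol(raw) >= 4) bed$name <- as.character(raw[[4]])
  validate_intervals(bed)
  bed
}

validate_intervals <- function(bed) {
  bad <- which(bed$start >= bed$end | bed$start < 0)
  if (length(bad) > 0) {
    abort_data(sprintf("invalid interval %s:%d-%d (need 0 <= start < end)",
                       bed$chrom[bad[1]], bed$start[bad[1]], bed$end[bad[1]]))
  }
  invisible(bed)
}

# 1-based point positions vs 0-based half-open intervals: position p is
# inside [start, end) iff start < p <= end after conversion to 1-based
# closed [start + 1, end].
iranges_of <- function(bed) IRanges::IRanges(start = bed$start + 1L, end = bed$end)

#' Test 1-based positions for interval membership
#'
#' @param chrom,pos Parallel vectors of chromosome and 1-based position.
#' @param bed Interval tibble as returned by [read_bed()].
#' @return Logical vector: is each position inside any interval?
#' @examples
#' bed <- tibble::tibble(chrom = "chr1", start = 99, end = 100)
#' in_intervals("chr1", c(99, 100), bed)  # FALSE TRUE
#' @export
in_intervals <- function(chrom, pos, bed) {
  validate_intervals(bed)
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    sub <- bed[bed$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (nrow(sub) == 0) next
    q <- IRanges::IRanges(start = pos[sel], width = 1L)
    out[sel] <- IRanges::overlapsAny(q, iranges_of(sub))
  }
  out
}

#' Map variants to named intervals
#'
#' Joins each variant position against a named interval track (gene
#' targets or exons). A position overlapping several intervals is
#' reported once per interval name, so a variant inside two genes'
#' targets contributes to both genes.
#'
#' @param variants Tibble with `chrom` and `pos` (1-based).
#' @param targets Interval tibble with `chrom`, `start`, `end`, `name`.
#' @param name_as Column name for the interval name in the output.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt` (when present) and the
#'   matched interval name; zero rows for unassigned variants.
#' @export
assign_intervals <- function(variants, targets, name_as = "gene_id") {
  if (!"name" %in% names(targets)) abort_config("interval track has no name column")
  validate_intervals(targets)
  v <- as_tibble(variants)
  keys <- intersect(c("chrom", "pos", "ref", "alt"), names(v))
  pieces <- list()
  for (ch in unique(v$chrom)) {
    sub <- targets[targets$chrom == ch, , drop = FALSE]
    vv <- v[v$chrom == ch, keys, drop = FALSE]
    if (nrow(sub) == 0 || nrow(vv) == 0) next
    hits <- IRanges::findOverlaps(IRanges::IRanges(start = vv$pos, width = 1L),
                                  iranges_of(sub))
    h <- as.data.frame(hits)
    if (nrow(h) == 0) next
    piece <- vv[h$queryHits, , drop = FALSE]
    piece[[name_as]] <- sub$name[h$subjectHits]
    pieces[[ch]] <- piece
  }
  if (length(pieces) == 0) {
    out <- v[0, keys, drop = FALSE]
    out[[name_as]] <- character(0)
    return(as_tibble(out))
  }
  dplyr::distinct(dplyr::bind_rows(pieces))
}
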