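#' The 16 variant strata
#'
#' Variants are cross-classified by predicted function and evolutionary
#' constraint. Functional classes: `Overall` (every variant), `Exon`
#' (coding), `DHS` (inside a DNase1-hypersensitivity interval), `Rare`
#' (reference-panel allele frequency below 0.01). Evolutionary classes:
#' `All` (every variant), `Cons` (GERP > 2), `Div` (GERP < -2), `Evo`
#' (either `Cons` or `Div`). A variant belongs to every stratum whose two
#' classes it satisfies, so membership is nested, not partitioned.
#'
#' @return A tibble with columns `functional`, `evolutionary` and `label`
#'   (`"<functional>_<evolutionary>"`), one row per stratum (16 rows).
#' @examples
#' stratum_labels()
#' @export
stratum_labels <- function() {
  grid <- tidyr::expand_grid(
    functional = c("Overall", "Exon", "DHS", "Rare"),
    evolutionary = c("All", "Cons", "Div", "Evo")
  )
  dplyr::mutate(grid, label = paste(.data$functional, .data$evolutionary, sep = "_"))
}

#' Classify GERP scores into conservation classes
#'
#' Scores above 2 are "conserved", below -2 "divergent"; anything else --
#' including a missing score -- is "neither". Both thresholds are strict,
#' so a score of exactly 2 or -2 is "neither".
#'
#' @param gerp Numeric vector of GERP RS scores; `NA` allowed.
#' @return Character vector in `c("conserved", "divergent", "neither")`.
#' @examples
#' gerp_class(c(3.1, -2.5, 2, NA))
#' @export
gerp_class <- function(gerp) {
  out <- rep("neither", length(gerp))
  out[!is.na(gerp) & gerp > 2] <- "conserved"
  out[!is.na(gerp) & gerp < -2] <- "divergent"
  out
}

# Ensure the annotation columns exist with documented defaults:
# missing ref_panel_af => 0 (private => rare), missing gerp => neither class.
ensure_annotation <- function(variants) {
  if (!"is_coding" %in% names(variants)) variants$is_coding <- FALSE
  if (!"is_synonymous" %in% names(variants)) variants$is_synonymous <- NA
  if (!"in_dhs" %in% names(variants)) variants$in_dhs <- FALSE
  if (!"gerp" %in% names(variants)) variants$gerp <- NA_real_
  if (!"ref_panel_af" %in% names(variants)) variants$ref_panel_af <- 0
  variants$ref_panel_af[is.na(variants$ref_panel_af)] <- 0
  if (any(variants$ref_panel_af < 0 | variants$ref_panel_af > 1)) {
    abort_data("ref_panel_af outside [0, 1]")
  }
  variants
}

#' Functional class membership
#'
#' @param variants Variant tibble with annotation columns `is_coding`,
#'   `in_dhs`, `ref_panel_af` (missing columns default to
#'   `FALSE`/`FALSE`/`0`).
#' @return The input with logical columns `f_Overall`, `f_Exon`, `f_DHS`,
#'   `f_Rare` added. `f_Overall` is always `TRUE`; `f_Rare` uses a strict
#'   `ref_panel_af < 0.01` cut, so a panel frequency of exactly 0.01 is
#'   not rare and a variant absent from the panel (frequency 0) is.
#' @export
functional_classes <- function(variants) {
  variants <- ensure_annotation(variants)
  dplyr::mutate(
    as_tibble(variants),
    f_Overall = TRUE,
    f_Exon = .data$is_coding %in% TRUE,
    f_DHS = .data$in_dhs %in% TRUE,
    f_Rare = .data$ref_panel_af < 0.01
  )
}

#' Assign variants to the 16 strata
#'
#' Adds one logical membership column per stratum label (see
#' [stratum_labels()]). Membership is the conjunction of the functional
#' and the evolutionary class, so the nesting properties hold by
#' construction: `Cons` or `Div` implies `Evo` implies `All`, and any
#' special functional class implies `Overall`.
#'
#' @param variants Variant tibble; annotation columns as in
#'   [functional_classes()] plus `gerp`.
#' @return The input tibble with 16 logical columns `Overall_All` ...
#'   `Rare_Evo` appended.
#' @examples
#' v <- tibble::tibble(is_coding = TRUE, in_dhs = FALSE,
#'                     gerp = 2.6, ref_panel_af = 0.002)
#' names(which(unlist(assign_strata(v)[stratum_labels()$label])))
#' @export
assign_strata <- function(variants) {
  v <- functional_classes(variants)
  gc <- gerp_class(v$gerp)
  evo <- list(
    All = rep(TRUE, nrow(v)),
    Cons = gc == "conserved",
    Div = gc == "divergent",
    Evo = gc != "neither"
  )
  fun <- list(Overall = v$f_Overall, Exon = v$f_Exon, DHS = v$f_DHS, Rare = v$f_Rare)
  for (f in names(fun)) {
    for (e in names(evo)) {
      v[[paste(f, e, sep = "_")]] <- fun[[f]] & evo[[e]]
    }
  }
  dplyr::select(v, -dplyr::all_of(c("f_Overall", "f_Exon", "f_DHS", "f_Rare")))
}

#' Marginal annotation fractions
#'
#' Summarises how a variant table splits across the annotation classes,
#' the quantities usually quoted for a targeted-sequencing design (e.g.
#' fraction coding, fraction in DHS, fraction evolutionarily constrained).
#'
#' @param variants Non-empty annotated variant tibble.
#' @return One-row tibble with columns `n`, `frac_coding`,
#'   `frac_synonymous_in_coding`, `frac_dhs`, `frac_evo`, `frac_rare`.
#' @export
annotation_summary <- function(variants) {
  if (nrow(as_tibble(variants)) == 0) abort_data("empty variant table")
  v <- ensure_annotation(variants)
  gc <- gerp_class(v$gerp)
  coding <- v$is_coding %in% TRUE
  syn <- v$is_synonymous %in% TRUE
  tibble(
    n = nrow(v),
    frac_coding = mean(coding),
    frac_synonymous_in_coding = if (any(coding)) mean(syn[coding]) else NA_real_,
    frac_dhs = mean(v$in_dhs %in% TRUE),
    frac_evo = mean(gc != "neither"),
    frac_rare = mean(v$ref_panel_af < 0.01)
  )
}

#' Annotate variants from external tracks
#'
#' Merges per-variant coding status, GERP scores, reference-panel allele
#' frequencies and DHS interval membership onto a variant table, then
#' assigns the 16 strata. Any track may be omitted, in which case the
#' corresponding default applies (non-coding, no GERP class, panel
#' frequency 0, not in DHS).
#'
#' @param variants Variant tibble with `chrom`, `pos`, `ref`, `alt`.
#' @param coding Optional tibble `chrom, pos, ref, alt, is_coding` and
#'   optionally `is_synonymous`.
#' @param gerp Optional tibble `chrom, pos, gerp`.
#' @param dhs Optional interval tibble `chrom, start, end` (0-based
#'   half-open, as read by [read_bed()]).
#' @param panel_af Optional tibble `chrom, pos, ref, alt, af`.
#' @return Annotated tibble with stratum membership columns.
#' @export
annotate_variants <- function(variants, coding = NULL, gerp = NULL,
                              dhs = NULL, panel_af = NULL) {
  v <- as_tibble(variants)
  if (!is.null(coding)) {
    keep <- c("chrom", "pos", "ref", "alt", "is_coding",
              intersect("is_synonymous", names(coding)))
    v <- dplyr::left_join(dplyr::select(v, -dplyr::any_of(c("is_coding", "is_synonymous"))),
                          dplyr::select(as_tibble(coding), dplyr::all_of(keep)),
                          by = c("chrom", "pos", "ref", "alt"))
    v$is_coding[is.na(v$is_coding)] <- FALSE
  }
  if (!is.null(gerp)) {
    v <- dplyr::left_join(dplyr::select(v, -dplyr::any_of("gerp")),
                          dplyr::select(as_tibble(gerp), "chrom", "pos", "gerp"),
                          by = c("chrom", "pos"))
  }
  if (!is.null(dhs)) {
    v$in_dhs <- in_intervals(v$chrom, v$pos, dhs)
  }
  if (!is.null(panel_af)) {
    af <- dplyr::rename(dplyr::select(as_tibble(panel_af), "chrom", "pos", "ref", "alt", "af"),
                        ref_panel_af = "af")
    v <- dplyr::left_join(dplyr::select(v, -dplyr::any_of("ref_panel_af")), af,
                          by = c("chrom", "pos", "ref", "alt"))
    v$ref_panel_af[is.na(v$ref_panel_af)] <- 0
  }
  assign_strata(v)
}
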