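#' Upper-tail chi-square probability
#'
#' Survival function of the chi-square distribution, accurate in the far
#' tail (relative accuracy well beyond 6 significant digits down to
#' p ~ 1e-300), as needed to report genome-wide-significant isoform
#' tests.
#'
#' @param chi2 Non-negative statistic.
#' @param df Degrees of freedom (>= 1).
#' @return `P[X >= chi2]` for `X ~ chi-square(df)`.
#' @examples
#' chi2_upper_tail(82.3, 16)
#' @export
chi2_upper_tail <- function(chi2, df) {
  if (any(df < 1)) abort_data("df must be >= 1")
  if (any(chi2 < 0)) abort_data("chi2 must be non-negative")
  pchisq(chi2, df, lower.tail = FALSE)
}

#' Filter variants qualifying for the reference-cohort comparison
#'
#' The comparison against a reference exome cohort uses coding variants
#' only, excludes common variants (reference allele frequency above
#' `max_af`), and excludes calls flagged low-confidence in the pooled
#' sequencing. Variants absent from the reference table are kept (their
#' frequency is treated as below any threshold).
#'
#' @param variants Variant tibble with `is_coding` and optionally a
#'   logical `low_confidence` column.
#' @param reference A `reference_cohort` object.
#' @param max_af Exclusion threshold on reference AF (default 0.01;
#'   variants with reference AF strictly above it are dropped).
#' @return The variant tibble with `ref_af` (NA when absent from the
#'   reference), logical `qualifying`, and `exclusion_reason`
#'   (`"noncoding"`, `"frequency"`, `"low-confidence"`, or NA) columns.
#' @export
qualifying_variants <- function(variants, reference, max_af = 0.01) {
  v <- as_tibble(variants)
  if (!"is_coding" %in% names(v)) abort_config("variants need an is_coding column")
  ref <- dplyr::rename(reference$af, ref_af = "af")
  v <- dplyr::left_join(dplyr::select(v, -dplyr::any_of("ref_af")), ref,
                        by = c("chrom", "pos", "ref", "alt"))
  lowconf <- if ("low_confidence" %in% names(v)) v$low_confidence %in% TRUE else rep(FALSE, nrow(v))
  reason <- rep(NA_character_, nrow(v))
  reason[!is.na(v$ref_af) & v$ref_af > max_af] <- "frequency"
  reason[lowconf] <- "low-confidence"
  reason[!(v$is_coding %in% TRUE)] <- "noncoding"
  v$exclusion_reason <- reason
  v$qualifying <- is.na(reason)
  v
}

#' Assign variants to isoforms by exon overlap
#'
#' A variant belongs to isoform i iff its 1-based position falls in one
#' of i's exons (stored 0-based half-open); a variant in an exon shared
#' by several isoforms belongs to each of them.
#'
#' @param gene_model Exon tibble for one gene (`chrom`, `start`, `end`,
#'   `isoform_id`; see [read_gene_models()]).
#' @param variants Variant tibble.
#' @return Tibble mapping `isoform_id` to variant keys; isoforms with no
#'   variant still appear in `attr(, "isoforms")`.
#' @export
assign_to_isoforms <- function(gene_model, variants) {
  gm <- validate_gene_models(as_tibble(gene_model))
  if (nrow(gm) == 0) abort_data("gene model has no exons")
  gm$name <- gm$isoform_id
  map <- assign_intervals(variants, gm, name_as = "isoform_id")
  attr(map, "isoforms") <- unique(gm$isoform_id)
  map
}

# Reference AF lookup with the private-variant floor 1/(2 n_ref).
reference_af_of <- function(variants, reference) {
  ref <- dplyr::rename(reference$af, .ref_af = "af")
  v <- dplyr::left_join(as_tibble(variants)[c("chrom", "pos", "ref", "alt")],
                        ref, by = c("chrom", "pos", "ref", "alt"))
  floor_af <- 1 / (2 * reference$n_individuals)
  ifelse(is.na(v$.ref_af), floor_af, v$.ref_af)
}

#' Expected allele counts per isoform
#'
#' The expected non-reference allele count for an isoform is the sum
#' over its qualifying variants of the reference-cohort allele frequency
#' times the number of alleles assayed in the comparison cohort:
#' `E = sum_v AF_ref(v) * A`. Variants absent from the reference take
#' the floor frequency `1/(2 * n_ref)` (one allele in the reference).
#'
#' @param isoform_variants Variant tibble for one isoform.
#' @param reference A `reference_cohort`.
#' @param cohort_alleles Total allele count A of the comparison arm
#'   (e.g. 37 pools x 16 individuals x 2 = 1184).
#' @return Expected count E (a real number).
#' @export
expected_counts <- function(isoform_variants, reference, cohort_alleles) {
  if (cohort_alleles <= 0) abort_data("cohort_alleles must be positive")
  if (nrow(as_tibble(isoform_variants)) == 0) return(0)
  sum(reference_af_of(isoform_variants, reference) * cohort_alleles)
}

#' Isoform-collapsed chi-square statistic
#'
#' Goodness-of-fit of observed to expected per-isoform allele counts:
#' `chi2 = sum_i (O_i - E_i)^2 / E_i` over isoforms with expectation
#' above `e_min`, with `df = n_included - 1` (multinomial convention).
#' Fewer than two includable isoforms is an untestable gene, reported
#' as such rather than an error.
#'
#' @param counts Tibble with columns `isoform_id`, `O`, `E`.
#' @param e_min Isoforms with `E < e_min` are excluded (default 1e-8).
#' @return One-row tibble: `chi2`, `df`, `n_included`, `testable`.
#' @export
isoform_chi2 <- function(counts, e_min = 1e-8) {
  counts <- as_tibble(counts)
  inc <- counts$E >= e_min
  n_inc <- sum(inc)
  if (n_inc < 2) {
    return(tibble(chi2 = NA_real_, df = NA_integer_,
                  n_included = n_inc, testable = FALSE))
  }
  chi2 <- sum((counts$O[inc] - counts$E[inc])^2 / counts$E[inc])
  tibble(chi2 = chi2, df = n_inc - 1L, n_included = n_inc, testable = TRUE)
}

#' Ratio score and residual diagnostics for one gene
#'
#' Combines the case-arm and control-arm isoform chi-square statistics
#' into the comparison score `chi2_case / chi2_control` (a score near 1
#' means cases deviate from the reference no more than controls do,
#' i.e. the deviation is technical; a large score localises true case
#' burden). Per-isoform residuals `(O - E)^2 / E` are reported for both
#' arms together with the adjusted residual (case residual / control
#' residual), which corrects each isoform for how far the null control
#' data already sit from the reference. Significance is the chi-square
#' upper tail of the case statistic, Bonferroni-corrected for `G`
#' genome-wide genes.
#'
#' @param case_counts,control_counts Tibbles `isoform_id`, `O`, `E` on
#'   the same isoform set.
#' @param gene_id Gene identifier for the report.
#' @param G Bonferroni gene count (default 20,000).
#' @param e_min Expectation floor below which an isoform is dropped from
#'   both arms symmetrically (df reduced).
#' @return An `isoform_test` object (see [run_isoform_test()]) with one
#'   gene.
#' @export
score_and_residuals <- function(case_counts, control_counts,
                                gene_id = "gene", G = 20000, e_min = 1e-8) {
  ca <- dplyr::arrange(as_tibble(case_counts), .data$isoform_id)
  co <- dplyr::arrange(as_tibble(control_counts), .data$isoform_id)
  if (!identical(ca$isoform_id, co$isoform_id)) {
    abort_data("case and control isoform sets differ")
  }
  inc <- ca$E >= e_min & co$E >= e_min
  iso <- tibble(
    gene_id = gene_id,
    isoform_id = ca$isoform_id,
    included = inc,
    O_case = ca$O, E_case = ca$E,
    O_control = co$O, E_control = co$E,
    resid_case = ifelse(inc, (ca$O - ca$E)^2 / ca$E, NA_real_),
    resid_control = ifelse(inc, (co$O - co$E)^2 / co$E, NA_real_)
  )
  iso$adjusted_residual <- ifelse(
    !inc, NA_real_,
    ifelse(iso$resid_control == 0, Inf, iso$resid_case / iso$resid_control)
  )
  n_inc <- sum(inc)
  if (n_inc >= 2) {
    chi2_case <- sum(iso$resid_case[inc])
    chi2_control <- sum(iso$resid_control[inc])
    df <- n_inc - 1L
    p <- chi2_upper_tail(chi2_case, df)
    gene <- tibble(
      gene_id = gene_id, n_isoforms = nrow(iso), n_included = n_inc,
      df = df, chi2_case = chi2_case, chi2_control = chi2_control,
      score = if (chi2_control == 0) Inf else chi2_case / chi2_control,
      p_uncorrected = p, p_corrected = min(1, G * p), testable = TRUE
    )
  } else {
    gene <- tibble(
      gene_id = gene_id, n_isoforms = nrow(iso), n_included = n_inc,
      df = NA_integer_, chi2_case = NA_real_, chi2_control = NA_real_,
      score = NA_real_, p_uncorrected = NA_real_, p_corrected = NA_real_,
      testable = FALSE
    )
  }
  new_isoform_test(gene, iso, G)
}

new_isoform_test <- function(genes, isoforms, G) {
  structure(list(genes = genes, isoforms = isoforms, G = G),
            class = "isoform_test")
}

#' @method print isoform_test
#' @export
print.isoform_test <- function(x, ...) {
  cat(sprintf("# Isoform-collapsed reference-cohort test: %d gene(s), Bonferroni G = %d\n",
              nrow(x$genes), x$G))
  print(x$genes)
  invisible(x)
}

#' Isoform-based comparison of a pooled cohort against a reference
#'
#' For each gene, qualifying coding variants (see
#' [qualifying_variants()]) are assigned to the gene's isoforms by exon
#' overlap; observed per-isoform allele counts are obtained from the
#' pooled rates (`O_i = r_arm * A_arm` summed over the isoform's
#' variants) and expected counts from the reference cohort's allele
#' frequencies scaled to the same allele total. Each arm (case,
#' control) is tested against the reference by the isoform-collapsed
#' chi-square, and the case/control ratio score plus adjusted residuals
#' flag genes -- and isoforms -- whose deviation is specific to cases.
#'
#' @param variants Variant tibble with pool-rate and coding columns.
#' @param design Pool design.
#' @param gene_models Exon tibble (`chrom`, `start`, `end`, `gene_id`,
#'   `isoform_id`).
#' @param reference A `reference_cohort`.
#' @param genes Optional character vector restricting the genes tested.
#' @param G Bonferroni genome-wide gene count (default 20,000).
#' @param max_af Reference-AF exclusion threshold (default 0.01).
#' @param e_min Expected-count floor for isoform inclusion.
#' @return An `isoform_test` object: `$genes` one row per gene,
#'   `$isoforms` per-isoform diagnostics, plus the exclusion report in
#'   `$excluded`.
#' @export
run_isoform_test <- function(variants, design, gene_models, reference,
                             genes = NULL, G = 20000, max_af = 0.01,
                             e_min = 1e-8) {
  design <- validate_pool_design(design)
  v <- validate_variants(variants, design)
  gm <- validate_gene_models(as_tibble(gene_models))
  if (is.null(genes)) genes <- unique(gm$gene_id)
  qv <- qualifying_variants(v, reference, max_af = max_af)
  kept <- qv[qv$qualifying, , drop = FALSE]
  kept <- group_rates(kept, design)
  a_case <- sum(design$alleles[design$label == "case"])
  a_ctrl <- sum(design$alleles[design$label == "control"])

  gene_rows <- list(); iso_rows <- list()
  for (g in genes) {
    model <- gm[gm$gene_id == g, , drop = FALSE]
    if (nrow(model) == 0) abort_config(paste0("no gene model for ", g))
    map <- assign_to_isoforms(model, kept)
    isoforms <- attr(map, "isoforms")
    counts <- function(arm_rate, A) {
      purrr::map_dfr(isoforms, function(iso) {
        keys <- map[map$isoform_id == iso, c("chrom", "pos", "ref", "alt")]
        vv <- dplyr::inner_join(kept, keys, by = c("chrom", "pos", "ref", "alt"))
        tibble(isoform_id = iso,
               O = sum(vv[[arm_rate]] * A),
               E = expected_counts(vv, reference, A))
      })
    }
    res <- score_and_residuals(counts("r_case", a_case), counts("r_ctrl", a_ctrl),
                               gene_id = g, G = G, e_min = e_min)
    gene_rows[[g]] <- res$genes
    iso_rows[[g]] <- res$isoforms
  }
  out <- new_isoform_test(dplyr::bind_rows(gene_rows), dplyr::bind_rows(iso_rows), G)
  out$excluded <- qv[!qv$qualifying, c("chrom", "pos", "ref", "alt", "exclusion_reason")]
  out
}
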