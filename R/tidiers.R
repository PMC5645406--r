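#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a burden result
#'
#' @param x A `polystrat_burden` object.
#' @param ... Unused.
#' @return A plain tibble, one row per (unit, stratum) test.
#' @export
tidy.polystrat_burden <- function(x, ...) {
  as_tibble(unclass_burden(x))
}

unclass_burden <- function(x) {
  attrs <- c("n_permutations", "mode", "family", "seed")
  for (a in attrs) attr(x, a) <- NULL
  class(x) <- setdiff(class(x), "polystrat_burden")
  x
}

#' One-row summary of a burden run
#'
#' @param x A `polystrat_burden` object.
#' @param alpha Significance level for the corrected-p count.
#' @param ... Unused.
#' @return Tibble with test counts, the permutation p-value floor, and
#'   the number of family-wise significant units.
#' @export
glance.polystrat_burden <- function(x, alpha = 0.05, ...) {
  B <- attr(x, "n_permutations")
  tibble(
    n_tests = nrow(x),
    n_units = dplyr::n_distinct(x$unit_id),
    n_strata = dplyr::n_distinct(x$stratum),
    n_permutations = B,
    mode = attr(x, "mode"),
    family = attr(x, "family"),
    p_floor = if (attr(x, "mode") == "monte_carlo") 1 / (B + 1) else NA_real_,
    n_significant = sum(x$p_corrected < alpha)
  )
}

#' @export
tidy.isoform_test <- function(x, ...) x$genes

#' @export
glance.isoform_test <- function(x, ...) {
  tibble(
    n_genes = nrow(x$genes),
    n_testable = sum(x$genes$testable),
    bonferroni_genes = x$G,
    n_significant = sum(x$genes$p_corrected < 0.05, na.rm = TRUE)
  )
}

#' Stratified p-value plot for a burden run
#'
#' One panel-free strip plot in the style of a per-category burden
#' summary: uncorrected p-values (as -log10) for every unit, grouped by
#' stratum, with the genome-wide Bonferroni reference line.
#'
#' @param object A `polystrat_burden` object.
#' @param genomewide_p Reference threshold drawn as a dashed line
#'   (default `0.05 / 20000`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.polystrat_burden <- function(object, genomewide_p = 0.05 / 20000, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$stratum, y = -log10(.data$p_uncorrected))) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(genomewide_p),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL, y = expression(-log[10](p)),
                  title = "Burden test p-values by stratum") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Per-isoform residual plot
#'
#' Case and control residuals `(O - E)^2 / E` per isoform, the
#' diagnostic used to localise a gene's burden to one isoform.
#'
#' @param object An `isoform_test` object.
#' @param gene Gene to plot (default: first).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.isoform_test <- function(object, gene = NULL, ...) {
  iso <- object$isoforms
  gene <- gene %||% iso$gene_id[1]
  d <- tidyr::pivot_longer(
    iso[iso$gene_id == gene, c("isoform_id", "resid_case", "resid_control")],
    cols = c("resid_case", "resid_control"),
    names_to = "arm", values_to = "residual"
  )
  d$arm <- ifelse(d$arm == "resid_case", "case", "control")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$isoform_id, y = .data$residual,
                                  fill = .data$arm)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = expression((O - E)^2 / E),
                  title = paste0("Isoform residuals: ", gene)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
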