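#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability that a random draw of `n` genes from a genome
#' of `N` contains at least `k` members of a set of size `K`:
#' `P[X >= k]` with `X ~ Hypergeometric(N, K, n)`. Used to pre-filter
#' gene sets for "at least weak" enrichment among the sequenced genes.
#'
#' @param K Set size in the genome.
#' @param k Overlap between the set and the targeted genes.
#' @param N Genome gene count (default 20,000).
#' @param n Number of targeted genes.
#' @return p in (0, 1]; `k = 0` gives exactly 1.
#' @export
hypergeometric_enrichment <- function(K, k, N, n) {
  if (any(k > pmin(K, n)) || any(n > N) || any(K > N) || any(k < 0)) {
    abort_data("inconsistent hypergeometric counts")
  }
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Enrichment pre-filter for gene sets
#'
#' Flags the sets worth burden-testing: those at least weakly enriched
#' (hypergeometric `enrichment_p < alpha`, strict) among the targeted
#' genes, with at least `min_targeted` targeted members (a one-gene set
#' would merely duplicate that gene's own test).
#'
#' @param sets Gene-set tibble from [read_gene_sets()] (`set_id`,
#'   `name`, list-column `genes`).
#' @param targeted_genes Character vector of sequenced gene ids.
#' @param genome_size Background gene count N (default 20,000).
#' @param alpha Enrichment threshold (default 0.1, strict).
#' @param min_targeted Minimum targeted members (default 2).
#' @return The set tibble with `n_targeted`, `enrichment_p` and logical
#'   `tested` columns added.
#' @export
filter_gene_sets <- function(sets, targeted_genes, genome_size = 20000,
                             alpha = 0.1, min_targeted = 2) {
  sets <- as_tibble(sets)
  targeted <- unique(targeted_genes)
  sets$n_targeted <- vapply(sets$genes, function(g) length(intersect(g, targeted)), 1L)
  sets$enrichment_p <- hypergeometric_enrichment(
    K = lengths(sets$genes), k = sets$n_targeted,
    N = genome_size, n = length(targeted)
  )
  sets$tested <- sets$enrichment_p < alpha & sets$n_targeted >= min_targeted
  sets
}

#' Set-level burden test
#'
#' Runs the burden test on gene sets: each tested set's statistic is the
#' burden statistic over the union of its member genes' variants, with a
#' variant shared by two member genes counted once. Permutation
#' p-values and minP correction reuse the same pool-relabeling
#' machinery as [run_polystrat()]; the correction family is the
#' collection of tested sets.
#'
#' @param sets Gene sets with `tested` flags (see [filter_gene_sets()]);
#'   sets with `tested = FALSE` are skipped. A plain set tibble without
#'   flags is tested in full.
#' @param variants Annotated variant tibble.
#' @param design Pool design.
#' @param targets Optional gene-target intervals (else `gene_id` column).
#' @param stratum Single stratum label restricting the variants used
#'   (default `"Overall_All"`, i.e. all variants).
#' @inheritParams run_polystrat
#' @return A `polystrat_burden` tibble with one row per testable set.
#' @export
run_set_burden <- function(sets, variants, design, targets = NULL,
                           stratum = "Overall_All",
                           n_permutations = 10000, seed = NULL,
                           exhaustive = NULL, exhaustive_cap = 10000) {
  design <- validate_pool_design(design)
  v <- validate_variants(variants, design)
  if (length(stratum) != 1 || !stratum %in% stratum_labels()$label) {
    abort_config("stratum must be a single stratum label")
  }
  if (!stratum %in% names(v)) v <- assign_strata(v)
  sets <- as_tibble(sets)
  if ("tested" %in% names(sets)) sets <- sets[sets$tested, ]
  if (nrow(sets) == 0) abort_data("no tested gene set")
  map <- gene_map_rows(v, targets)
  in_s <- which(v[[stratum]])

  units <- list(); keep <- logical(nrow(sets))
  for (i in seq_len(nrow(sets))) {
    rows <- unique(map$row[map$gene_id %in% sets$genes[[i]]])
    rows <- intersect(rows, in_s)
    if (length(rows) == 0) next
    keep[i] <- TRUE
    units[[length(units) + 1]] <- rows
  }
  if (length(units) == 0) abort_data("no set has variants in the chosen stratum")
  res <- burden_units(v, design, units, n_permutations, seed,
                      exhaustive, exhaustive_cap)
  out <- dplyr::bind_cols(
    tibble(unit_id = sets$set_id[keep], stratum = stratum),
    res
  )
  out <- dplyr::arrange(out, .data$p_corrected, .data$p_uncorrected, .data$unit_id)
  new_polystrat_burden(out, n_permutations = n_permutations,
                       mode = attr(res, "mode"), family = "sets", seed = seed)
}
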