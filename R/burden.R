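#' Pooled case and control allele rates per variant
#'
#' Collapses per-pool non-reference allele rates into one rate per arm,
#' weighting each pool by its allele count (`2 * n_individuals`):
#' `r_arm = sum(rate_p * alleles_p) / sum(alleles_p)`. With equal pool
#' sizes this is the plain mean of the pool rates.
#'
#' @param variants Variant tibble with one rate column per pool.
#' @param design Pool design tibble.
#' @return The variant tibble with numeric columns `r_case` and `r_ctrl`
#'   appended.
#' @examples
#' d <- pool_design(n_case = 2, n_control = 2, pool_size = 16)
#' v <- tibble::tibble(chrom = "chr1", pos = 1L, ref = "A", alt = "G",
#'                     case_01 = 0.10, case_02 = 0.00,
#'                     ctrl_01 = 0.05, ctrl_02 = 0.05)
#' group_rates(v, d)[, c("r_case", "r_ctrl")]
#' @export
group_rates <- function(variants, design) {
  design <- validate_pool_design(design)
  v <- validate_variants(variants, design)
  for (arm in c("case", "control")) {
    pools <- design[design$label == arm, ]
    if (nrow(pools) == 0) abort_data(paste0("no ", arm, " pools in design"))
    r <- as.matrix(v[pools$pool_id]) %*% pools$alleles / sum(pools$alleles)
    v[[if (arm == "case") "r_case" else "r_ctrl"]] <- as.numeric(r)
  }
  v
}

#' Burden statistic for one variant set
#'
#' The burden statistic for a gene (or any unit) is the sum over its
#' variants of the case minus control pooled allele-rate difference:
#' `S = sum_v (r_case(v) - r_ctrl(v))`. A positive S means an excess of
#' non-reference alleles in cases. The empty set gives `S = 0` with
#' `n_variants = 0` (untestable).
#'
#' @param variants Variants already filtered to the unit (gene and
#'   stratum) under test.
#' @param design Pool design.
#' @return One-row tibble: `statistic`, `n_variants`, `n_case_abundant`
#'   (variants with a strictly higher case rate).
#' @export
burden_statistic <- function(variants, design) {
  if (nrow(as_tibble(variants)) == 0) {
    return(tibble(statistic = 0, n_variants = 0L, n_case_abundant = 0L))
  }
  v <- group_rates(variants, design)
  d <- v$r_case - v$r_ctrl
  tibble(statistic = sum(d), n_variants = length(d),
         n_case_abundant = sum(d > 0))
}

# --- permutation machinery ---------------------------------------------

#' Case/control label permutations over pools
#'
#' Builds the case-indicator matrix used by the permutation test: column
#' 1 is the observed labeling; the remaining columns are relabelings of
#' the pools preserving the case/control counts. In Monte-Carlo mode
#' these are `n_permutations` uniform draws; in exhaustive mode every
#' distinct arrangement is enumerated exactly once (the identity
#' included). Exhaustive mode is auto-selected when the number of
#' arrangements is at most `exhaustive_cap`.
#'
#' @param design Pool design (needs at least 2 pools per arm).
#' @param n_permutations Monte-Carlo permutation count B.
#' @param seed Optional integer seed (local to this call).
#' @param exhaustive `TRUE`, `FALSE`, or `NULL` to auto-select.
#' @param exhaustive_cap Arrangement count above which auto-selection
#'   falls back to Monte-Carlo.
#' @return Logical matrix of dimension pools x (1 + draws) with
#'   attributes `mode` (`"monte_carlo"` or `"exhaustive"`).
#' @export
permutation_labels <- function(design, n_permutations = 10000, seed = NULL,
                               exhaustive = NULL, exhaustive_cap = 10000) {
  design <- validate_pool_design(design)
  obs <- design$label == "case"
  n_case <- sum(obs)
  n_pool <- length(obs)
  if (n_case < 2 || n_pool - n_case < 2) {
    abort_data("permutation test needs at least 2 pools per arm")
  }
  total <- choose(n_pool, n_case)
  use_ex <- exhaustive %||% (total <= exhaustive_cap)
  if (use_ex && total > exhaustive_cap) {
    abort_config(sprintf("exhaustive enumeration of %.0f arrangements exceeds cap %d",
                         total, exhaustive_cap))
  }
  if (use_ex) {
    idx <- combn(n_pool, n_case)
    null_mat <- matrix(FALSE, n_pool, ncol(idx))
    null_mat[cbind(as.vector(idx), rep(seq_len(ncol(idx)), each = n_case))] <- TRUE
  } else {
    draw <- function() {
      m <- matrix(FALSE, n_pool, n_permutations)
      for (b in seq_len(n_permutations)) {
        m[sample.int(n_pool, n_case), b] <- TRUE
      }
      m
    }
    null_mat <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  }
  structure(cbind(obs, null_mat, deparse.level = 0),
            mode = if (use_ex) "exhaustive" else "monte_carlo")
}

# Per-variant case-minus-control rate differences under every labeling.
# rates: V x P, alleles: length P, labels: P x (1 + n_null) logical.
rate_diff_matrix <- function(rates, alleles, labels) {
  wc <- alleles * labels
  ww <- alleles * !labels
  dc <- rates %*% wc
  dw <- rates %*% ww
  sweep(dc, 2, colSums(wc), "/") - sweep(dw, 2, colSums(ww), "/")
}

# #{null values >= v} for each v, exact under ties.
count_ge <- function(values, null_values) {
  s <- sort(null_values)
  length(s) - findInterval(values, s, left.open = TRUE)
}

#' Permutation p-value for one test
#'
#' One-sided, upper tail, ties counted as extreme. Monte-Carlo mode uses
#' the add-one convention `p = (#{T_b >= T_obs} + 1) / (B + 1)`, so p is
#' floored at `1/(B + 1)` (1e-4 at the default B = 10,000). Exhaustive
#' mode uses `p = #{arrangements with T >= T_obs} / total`; the identity
#' arrangement is always counted, so p >= 1/total.
#'
#' @param observed Observed statistic.
#' @param null_values Statistics under the label permutations (for
#'   exhaustive mode, all arrangements including the identity).
#' @param mode `"monte_carlo"` or `"exhaustive"`.
#' @return p-value in (0, 1].
#' @export
permutation_pvalue <- function(observed, null_values,
                               mode = c("monte_carlo", "exhaustive")) {
  mode <- match.arg(mode)
  cnt <- count_ge(observed, null_values)
  if (mode == "monte_carlo") (cnt + 1) / (length(null_values) + 1) else cnt / length(null_values)
}

perm_pvalue_rows <- function(T_mat, mode) {
  nn <- ncol(T_mat) - 1
  p <- vapply(seq_len(nrow(T_mat)), function(t) {
    cnt <- count_ge(T_mat[t, 1], T_mat[t, -1])
    if (mode == "monte_carlo") (cnt + 1) / (nn + 1) else cnt / nn
  }, 1.0)
  p
}

#' Single-step minP family-wise correction
#'
#' Westfall-Young empirical correction sharing one permutation stream
#' across all tests in the family, which preserves their correlation.
#' For each labeling `b`, every test's statistic is converted into a
#' pseudo p-value by ranking it within that test's own permutation
#' distribution (same upper-tail, ties-as-extreme convention as
#' [permutation_pvalue()]); `m(b)` is the minimum pseudo p across tests;
#' the corrected p for test t is the permutation probability that `m(b)`
#' is at most t's uncorrected p. The result is monotone (corrected >=
#' uncorrected), order-preserving, and bounded by 1.
#'
#' @param T_mat Statistic matrix, one row per test in the family; column
#'   1 holds the observed statistics, the remaining columns the shared
#'   permutation replicates.
#' @param mode `"monte_carlo"` or `"exhaustive"` (must match how the
#'   columns were generated).
#' @return Tibble with `p_uncorrected` and `p_corrected`, one row per
#'   test.
#' @export
minp_correct <- function(T_mat, mode = c("monte_carlo", "exhaustive")) {
  mode <- match.arg(mode)
  T_mat <- rbind(T_mat)
  nn <- ncol(T_mat) - 1
  pseudo <- matrix(0, nrow(T_mat), nn + 1)
  for (t in seq_len(nrow(T_mat))) {
    cnt <- count_ge(T_mat[t, ], T_mat[t, -1])
    pseudo[t, ] <- if (mode == "monte_carlo") (cnt + 1) / (nn + 1) else cnt / nn
  }
  p0 <- pseudo[, 1]
  m <- apply(pseudo[, -1, drop = FALSE], 2, min)
  cnt_le <- findInterval(p0, sort(m))
  p_corr <- if (mode == "monte_carlo") (cnt_le + 1) / (nn + 1) else cnt_le / nn
  tibble(p_uncorrected = p0, p_corrected = pmin(1, pmax(p_corr, p0)))
}

# --- full stratified run -----------------------------------------------

# Build the variant-to-gene map as row indices into the variant table.
gene_map_rows <- function(variants, targets) {
  if (!is.null(targets)) {
    map <- assign_intervals(variants, targets, "gene_id")
    if (nrow(map) == 0) abort_data("no variant falls in any gene target")
    map$row <- match(variant_key(map), variant_key(variants))
    map[c("row", "gene_id")]
  } else if ("gene_id" %in% names(variants)) {
    map <- tibble(row = seq_len(nrow(variants)), gene_id = variants$gene_id)
    map[!is.na(map$gene_id), ]
  } else {
    abort_config("supply gene targets or a gene_id column")
  }
}

#' Run the annotation-stratified burden test
#'
#' For every (gene, stratum) unit with at least one variant, computes
#' the burden statistic (see [burden_statistic()]), a one-sided
#' permutation p-value over pool-label permutations, and an empirical
#' family-wise corrected p-value by the single-step minP procedure.
#' One shared permutation stream serves every unit, which is what makes
#' the minP correction valid across correlated tests. Because each
#' gene is ranked against its own permutation distribution, the test is
#' calibrated regardless of how many variants the gene contains.
#'
#' @param variants Annotated variant tibble (stratum membership columns
#'   are computed on the fly when absent).
#' @param design Pool design.
#' @param targets Optional gene-target interval tibble (`chrom`,
#'   `start`, `end`, `name`); when `NULL`, a `gene_id` column on
#'   `variants` is used. A variant inside two genes' targets is tested
#'   in both.
#' @param strata Character vector of stratum labels to test (default all
#'   16).
#' @param n_permutations Monte-Carlo permutation count B (default
#'   10,000, giving a p-value floor of 1e-4).
#' @param seed Optional integer seed for the permutation stream.
#' @param exhaustive `TRUE`/`FALSE`/`NULL` (auto); see
#'   [permutation_labels()].
#' @param exhaustive_cap Auto-selection cap on arrangement count.
#' @param family `"experiment"` corrects across all gene-by-stratum
#'   tests jointly (experiment-wide significance); `"stratum"` corrects
#'   within each stratum separately.
#' @return A `polystrat_burden` tibble: `unit_id`, `stratum`,
#'   `n_variants`, `n_case_abundant`, `statistic`, `p_uncorrected`,
#'   `p_corrected`, sorted by corrected then uncorrected p.
#' @export
run_polystrat <- function(variants, design, targets = NULL,
                          strata = stratum_labels()$label,
                          n_permutations = 10000, seed = NULL,
                          exhaustive = NULL, exhaustive_cap = 10000,
                          family = c("experiment", "stratum")) {
  family <- match.arg(family)
  design <- validate_pool_design(design)
  v <- validate_variants(variants, design)
  if (!all(strata %in% stratum_labels()$label)) {
    abort_config("unknown stratum label")
  }
  if (!all(strata %in% names(v))) v <- assign_strata(v)
  map <- gene_map_rows(v, targets)

  units <- list(); unit_meta <- list()
  for (s in strata) {
    in_s <- which(v[[s]])
    sub <- map[map$row %in% in_s, ]
    if (nrow(sub) == 0) next
    by_gene <- split(sub$row, sub$gene_id)
    for (g in names(by_gene)) {
      units[[length(units) + 1]] <- by_gene[[g]]
      unit_meta[[length(unit_meta) + 1]] <- tibble(unit_id = g, stratum = s)
    }
  }
  if (length(units) == 0) abort_data("no testable (gene, stratum) unit")
  meta <- dplyr::bind_rows(unit_meta)

  res <- burden_units(v, design, units, n_permutations, seed,
                      exhaustive, exhaustive_cap,
                      family_of = if (family == "stratum") meta$stratum else NULL)
  out <- dplyr::arrange(dplyr::bind_cols(meta, res),
                        .data$p_corrected, .data$p_uncorrected, .data$unit_id)
  new_polystrat_burden(out, n_permutations = n_permutations,
                       mode = attr(res, "mode"), family = family, seed = seed)
}

# Shared engine: units is a list of variant row-index vectors.
burden_units <- function(v, design, units, n_permutations, seed,
                         exhaustive, exhaustive_cap, family_of = NULL) {
  rates <- as.matrix(v[design$pool_id])
  labels <- permutation_labels(design, n_permutations, seed, exhaustive, exhaustive_cap)
  mode <- attr(labels, "mode")
  D <- rate_diff_matrix(rates, design$alleles, labels)
  A <- Matrix::sparseMatrix(
    i = rep(seq_along(units), lengths(units)),
    j = unlist(units), x = 1,
    dims = c(length(units), nrow(v))
  )
  T_mat <- as.matrix(A %*% D)
  if (is.null(family_of)) {
    mp <- minp_correct(T_mat, mode)
  } else {
    mp <- tibble(p_uncorrected = rep(NA_real_, nrow(T_mat)),
                 p_corrected = NA_real_)
    for (f in unique(family_of)) {
      sel <- family_of == f
      mp[sel, ] <- minp_correct(T_mat[sel, , drop = FALSE], mode)
    }
  }
  res <- tibble(
    n_variants = lengths(units),
    n_case_abundant = as.integer(A %*% (D[, 1] > 0)),
    statistic = T_mat[, 1],
    p_uncorrected = mp$p_uncorrected,
    p_corrected = mp$p_corrected
  )
  attr(res, "mode") <- mode
  res
}

new_polystrat_burden <- function(x, n_permutations, mode, family, seed) {
  structure(x, class = c("polystrat_burden", class(x)),
            n_permutations = n_permutations, mode = mode,
            family = family, seed = seed)
}

#' @method print polystrat_burden
#' @export
print.polystrat_burden <- function(x, ...) {
  floor_p <- if (attr(x, "mode") == "monte_carlo") {
    1 / (attr(x, "n_permutations") + 1)
  } else NA_real_
  cat(sprintf("# Burden test: %d units, %s permutations (%s family), p floor %s\n",
              nrow(x), format(attr(x, "n_permutations")), attr(x, "family"),
              format(floor_p, digits = 3)))
  NextMethod()
}
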