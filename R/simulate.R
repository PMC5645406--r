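#' Case-arm allele frequency implied by an odds ratio
#'
#' Effects are planted on the odds scale: if the control-arm frequency
#' is `p0`, the case-arm frequency solves
#' `odds(p1) = OR * odds(p0)`, i.e. `p1 = OR*o0 / (1 + OR*o0)` with
#' `o0 = p0/(1-p0)`. This keeps `p1` in (0, 1) for any positive OR.
#'
#' @param p0 Control-arm allele frequency.
#' @param odds_ratio Odds ratio (> 0).
#' @return Case-arm allele frequency.
#' @examples
#' case_af_from_or(0.022, 2.4)  # ~0.0512
#' @export
case_af_from_or <- function(p0, odds_ratio) {
  if (any(odds_ratio <= 0)) abort_data("odds_ratio must be positive")
  o <- odds_ratio * p0 / (1 - p0)
  o / (1 + o)
}

#' Define a synthetic pooled-sequencing scenario
#'
#' Captures the generative parameters of a pooled case-control study.
#' Defaults reproduce the reference study geometry: 37 case and 35
#' control pools of 16 individuals (592 cases, 560 controls), a
#' rare-skewed Beta(0.2, 4) population allele-frequency distribution,
#' and annotation marginals of 16% coding, 36% DHS and 80%
#' conserved-or-divergent.
#'
#' @param n_case_pools,n_control_pools,pool_size Pool geometry.
#' @param n_genes Number of genes simulated.
#' @param variants_per_gene Mean of the per-gene Poisson variant count
#'   (floored at 1).
#' @param af_alpha,af_beta Beta parameters of the population AF
#'   distribution.
#' @param coding_frac,dhs_frac,evo_frac Annotation marginals.
#' @param cons_frac_within_evo Fraction of constrained variants that are
#'   conserved rather than divergent.
#' @param syn_frac_within_coding Fraction of coding variants that are
#'   synonymous.
#' @param planted Tibble of planted signals: `gene_id`, `odds_ratio`,
#'   optional `target_af` (control-arm AF forced onto the gene's
#'   variants) and optional `stratum` (annotations forced so the gene's
#'   variants belong to that stratum).
#' @param planting `"odds"` (logistic effect, default) or `"additive"`
#'   (requires a `delta` column in `planted`; `p1 = p0 + delta`).
#' @param noise_sd SD of the truncated-Gaussian sequencing noise added
#'   to each pool rate (default 0.01).
#' @param seed Optional integer seed; same seed, same cohort.
#' @return A `polystrat_scenario` list.
#' @export
polystrat_scenario <- function(n_case_pools = 37, n_control_pools = 35,
                               pool_size = 16, n_genes = 50,
                               variants_per_gene = 10,
                               af_alpha = 0.2, af_beta = 4,
                               coding_frac = 0.16, dhs_frac = 0.36,
                               evo_frac = 0.80, cons_frac_within_evo = 0.7,
                               syn_frac_within_coding = 0.51,
                               planted = NULL, planting = c("odds", "additive"),
                               noise_sd = 0.01, seed = NULL) {
  planting <- match.arg(planting)
  marg <- c(coding_frac, dhs_frac, evo_frac, cons_frac_within_evo,
            syn_frac_within_coding)
  if (any(marg < 0 | marg > 1)) abort_data("annotation marginals must lie in [0, 1]")
  if (n_case_pools < 2 || n_control_pools < 2) {
    abort_data("need at least 2 pools per arm")
  }
  if (noise_sd < 0) abort_data("noise_sd must be non-negative")
  if (!is.null(planted)) {
    planted <- as_tibble(planted)
    if (any(planted$odds_ratio <= 0)) abort_data("planted odds_ratio must be positive")
  }
  structure(
    list(n_case_pools = n_case_pools, n_control_pools = n_control_pools,
         pool_size = pool_size, n_genes = n_genes,
         variants_per_gene = variants_per_gene,
         af_alpha = af_alpha, af_beta = af_beta,
         coding_frac = coding_frac, dhs_frac = dhs_frac, evo_frac = evo_frac,
         cons_frac_within_evo = cons_frac_within_evo,
         syn_frac_within_coding = syn_frac_within_coding,
         planted = planted, planting = planting,
         noise_sd = noise_sd, seed = seed),
    class = "polystrat_scenario"
  )
}

rgerp <- function(n, evo_frac, cons_frac) {
  evo <- runif(n) < evo_frac
  cons <- runif(n) < cons_frac
  mag <- runif(n, 2.2, 6)
  ifelse(evo, ifelse(cons, mag, -mag), runif(n, -1.9, 1.9))
}

# Draw pool rates for one arm: binomial allele counts per pool plus
# truncated Gaussian sequencing noise on the rate scale.
draw_pool_rates <- function(p_arm, pools, noise_sd) {
  n_v <- length(p_arm)
  m <- matrix(0, n_v, nrow(pools))
  for (j in seq_len(nrow(pools))) {
    cnt <- rbinom(n_v, pools$alleles[j], p_arm)
    r <- cnt / pools$alleles[j]
    if (noise_sd > 0) r <- r + rnorm(n_v, 0, noise_sd)
    m[, j] <- pmin(1, pmax(0, r))
  }
  colnames(m) <- pools$pool_id
  m
}

force_stratum <- function(variants, rows, stratum) {
  parts <- strsplit(stratum, "_", fixed = TRUE)[[1]]
  f <- parts[1]; e <- parts[2]
  if (f == "Exon") variants$is_coding[rows] <- TRUE
  if (f == "DHS") variants$in_dhs[rows] <- TRUE
  if (f == "Rare") variants$ref_panel_af[rows] <- pmin(variants$ref_panel_af[rows], 0.009)
  if (e %in% c("Cons", "Evo")) variants$gerp[rows] <- runif(length(rows), 2.2, 6)
  if (e == "Div") variants$gerp[rows] <- -runif(length(rows), 2.2, 6)
  variants
}

#' Simulate a pooled case-control cohort
#'
#' Generates a full synthetic study from a scenario: a pool design, a
#' gene-target track, and a variant table with per-pool non-reference
#' allele rates and annotations. For each variant a population
#' (control-arm) frequency `p0` is drawn from the scenario's Beta
#' distribution; planted genes get a case-arm frequency shifted on the
#' odds scale by the planted OR, all other variants are null
#' (`p1 = p0`). Pool allele counts are binomial in `2 * pool_size`
#' draws at the arm frequency, and the observed rate adds truncated
#' Gaussian sequencing noise. Annotations are drawn independently at
#' the scenario marginals; the reference-panel AF mirrors `p0`.
#'
#' @param scenario A [polystrat_scenario()].
#' @return List with `variants` (annotated, with `gene_id`), `design`,
#'   `targets` (0-based half-open gene intervals), and `truth` (the
#'   planted table, empty under the null).
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "polystrat_scenario"))
  run <- function() simulate_cohort_impl(scenario)
  if (is.null(scenario$seed)) run() else withr::with_seed(scenario$seed, run())
}

simulate_cohort_impl <- function(sc) {
  design <- pool_design(sc$n_case_pools, sc$n_control_pools, sc$pool_size)
  gene_ids <- sprintf("G%04d", seq_len(sc$n_genes))
  n_v <- pmax(1L, rpois(sc$n_genes, sc$variants_per_gene))
  gene_of <- rep(gene_ids, n_v)
  block <- rep(seq_len(sc$n_genes) - 1L, n_v) * 100000L
  offset <- unlist(lapply(n_v, function(k) sort(sample.int(99000L, k))))
  total <- length(gene_of)

  p0 <- rbeta(total, sc$af_alpha, sc$af_beta)
  p1 <- p0
  planted <- sc$planted
  if (!is.null(planted) && nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      rows <- which(gene_of == planted$gene_id[i])
      if (length(rows) == 0) abort_config(paste0("planted gene not simulated: ",
                                                 planted$gene_id[i]))
      if ("target_af" %in% names(planted) && !is.na(planted$target_af[i])) {
        p0[rows] <- planted$target_af[i]
      }
      if (sc$planting == "odds") {
        p1[rows] <- case_af_from_or(p0[rows], planted$odds_ratio[i])
      } else {
        if (!"delta" %in% names(planted)) {
          abort_config("additive planting needs a delta column")
        }
        p1[rows] <- p0[rows] + planted$delta[i]
        bad <- rows[p1[rows] > 1]
        if (length(bad) > 0) {
          abort_data(sprintf("infeasible planted frequency > 1 at chr1:%d",
                             block[bad[1]] + offset[bad[1]]))
        }
      }
    }
  }

  case_pools <- design[design$label == "case", ]
  ctrl_pools <- design[design$label == "control", ]
  rates <- cbind(draw_pool_rates(p1, case_pools, sc$noise_sd),
                 draw_pool_rates(p0, ctrl_pools, sc$noise_sd))

  variants <- tibble(
    chrom = "chr1", pos = block + offset, ref = "A", alt = "G",
    gene_id = gene_of
  )
  variants <- dplyr::bind_cols(variants, as_tibble(rates))
  variants$is_coding <- runif(total) < sc$coding_frac
  variants$is_synonymous <- ifelse(variants$is_coding,
                                   runif(total) < sc$syn_frac_within_coding, NA)
  variants$in_dhs <- runif(total) < sc$dhs_frac
  variants$gerp <- rgerp(total, sc$evo_frac, sc$cons_frac_within_evo)
  variants$ref_panel_af <- p0
  if (!is.null(planted) && "stratum" %in% names(planted)) {
    for (i in seq_len(nrow(planted))) {
      if (is.na(planted$stratum[i])) next
      rows <- which(gene_of == planted$gene_id[i])
      variants <- force_stratum(variants, rows, planted$stratum[i])
    }
  }

  targets <- tibble(
    chrom = "chr1",
    start = (seq_len(sc$n_genes) - 1L) * 100000L,
    end = (seq_len(sc$n_genes) - 1L) * 100000L + 99000L,
    name = gene_ids
  )
  truth <- if (is.null(planted)) {
    tibble(gene_id = character(0), odds_ratio = numeric(0))
  } else planted
  list(variants = variants, design = design, targets = targets, truth = truth)
}

#' Simulate an isoform-structured gene fixture
#'
#' Builds the inputs for the isoform-collapsed reference-cohort test:
#' a gene with `n_isoforms` isoform-specific exons, coding variants with
#' reference allele frequencies drawn uniformly from `af_range`, and
#' pooled case/control rate columns whose implied per-isoform observed
#' counts are multinomial at the reference expectations -- except that
#' `excess` extra non-reference alleles are planted into
#' `planted_isoform`'s case counts. With `excess = 0` the case arm is
#' an exact draw from the null, so the case chi-square follows the
#' chi-square distribution with `n_isoforms - 1` degrees of freedom.
#'
#' @param n_isoforms Number of isoforms (>= 2).
#' @param variants_per_isoform Coding variants per isoform.
#' @param af_range Range of reference allele frequencies (kept within
#'   the qualifying cut of 0.01).
#' @param design Pool design (default: study geometry).
#' @param reference_n Reference cohort size (default 33,370).
#' @param planted_isoform Isoform index receiving planted excess, or
#'   `NULL`.
#' @param excess Extra observed case alleles planted (non-negative).
#' @param seed Optional integer seed.
#' @return List with `gene_model`, `variants`, `design`, `reference`,
#'   `case_counts` / `control_counts` (per-isoform `O`/`E` tibbles) and
#'   `truth`.
#' @export
simulate_isoform_gene <- function(n_isoforms = 17, variants_per_isoform = 3,
                                  af_range = c(0.001, 0.01),
                                  design = pool_design(),
                                  reference_n = 33370,
                                  planted_isoform = NULL, excess = 0,
                                  seed = NULL) {
  if (n_isoforms < 2) abort_data("need at least 2 isoforms")
  run <- function() {
    simulate_isoform_impl(n_isoforms, variants_per_isoform, af_range, design,
                          reference_n, planted_isoform, excess)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

# Spread `count` alleles over an arm's pools by sampling allele slots
# without replacement, so no pool exceeds its allele capacity and the
# implied observed count round-trips exactly.
spread_alleles <- function(count, pools) {
  slots <- rep(seq_len(nrow(pools)), pools$alleles)
  cnt <- tabulate(sample(slots, count), nbins = nrow(pools))
  cnt / pools$alleles
}

simulate_isoform_impl <- function(n_isoforms, vpi, af_range, design,
                                  reference_n, planted_isoform, excess) {
  iso_ids <- sprintf("iso_%02d", seq_len(n_isoforms))
  gene_model <- tibble(
    chrom = "chr2",
    start = seq_len(n_isoforms) * 10000L,
    end = seq_len(n_isoforms) * 10000L + 1000L,
    gene_id = "GENE1", isoform_id = iso_ids
  )
  variants <- purrr::map_dfr(seq_len(n_isoforms), function(i) {
    tibble(chrom = "chr2",
           pos = gene_model$start[i] + seq_len(vpi) * 10L,
           ref = "A", alt = "G", isoform = iso_ids[i],
           af = runif(vpi, af_range[1], af_range[2]))
  })
  reference <- reference_cohort(
    dplyr::select(variants, "chrom", "pos", "ref", "alt", "af"),
    name = "synthetic_reference", n_individuals = reference_n
  )

  case_pools <- design[design$label == "case", ]
  ctrl_pools <- design[design$label == "control", ]
  a_case <- sum(case_pools$alleles)
  a_ctrl <- sum(ctrl_pools$alleles)

  draw_arm <- function(A, pools, planted = NULL, extra = 0) {
    E_v <- variants$af * A
    E_iso <- tapply(E_v, variants$isoform, sum)[iso_ids]
    N <- round(sum(E_iso))
    O_iso <- as.vector(rmultinom(1, N, E_iso / sum(E_iso)))
    names(O_iso) <- iso_ids
    if (!is.null(planted)) O_iso[planted] <- O_iso[planted] + extra
    # split isoform counts over its variants, then over the arm's pools
    rate_mat <- matrix(0, nrow(variants), nrow(pools))
    for (i in seq_len(n_isoforms)) {
      rows <- which(variants$isoform == iso_ids[i])
      split_v <- as.vector(rmultinom(1, O_iso[i], variants$af[rows]))
      for (j in seq_along(rows)) {
        rate_mat[rows[j], ] <- spread_alleles(split_v[j], pools)
      }
    }
    colnames(rate_mat) <- pools$pool_id
    list(rates = rate_mat,
         counts = tibble(isoform_id = iso_ids, O = as.numeric(O_iso),
                         E = as.numeric(E_iso)))
  }
  case <- draw_arm(a_case, case_pools, planted_isoform, excess)
  ctrl <- draw_arm(a_ctrl, ctrl_pools)

  vtab <- dplyr::bind_cols(
    dplyr::select(variants, "chrom", "pos", "ref", "alt"),
    as_tibble(case$rates), as_tibble(ctrl$rates)
  )
  vtab$is_coding <- TRUE
  vtab$ref_panel_af <- variants$af
  list(gene_model = gene_model, variants = vtab, design = design,
       reference = reference, case_counts = case$counts,
       control_counts = ctrl$counts,
       truth = list(planted_isoform = planted_isoform, excess = excess))
}
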