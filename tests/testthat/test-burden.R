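test_that("arm rates are allele-weighted means of pool rates", {
  # equal pools: plain mean
  d <- pool_design(2, 2, 16)
  v <- variants_from_rates(matrix(c(0.10, 0.00, 0.05, 0.05), 1), d)
  r <- group_rates(v, d)
  expect_equal(r$r_case, 0.05)
  expect_equal(r$r_ctrl, 0.05)

  # unequal pools of 16 and 8 individuals: (0*32 + 0.5*16) / 48 = 1/6
  d2 <- tibble::tibble(pool_id = c("a", "b", "c", "d"),
                       label = c("case", "case", "control", "control"),
                       n_individuals = c(16L, 8L, 16L, 8L),
                       alleles = c(32L, 16L, 32L, 16L))
  v2 <- variants_from_rates(matrix(c(0, 0.5, 1, 1), 1), d2)
  r2 <- group_rates(v2, d2)
  expect_equal(r2$r_case, 1 / 6)
  expect_equal(r2$r_ctrl, 1)
})

test_that("burden statistic sums rate differences and counts case-abundant variants", {
  d <- pool_design(2, 2, 16)
  rates <- rbind(c(0.10, 0.10, 0.02, 0.02),   # diff +0.08
                 c(0.05, 0.05, 0.05, 0.05))   # diff 0
  s <- burden_statistic(variants_from_rates(rates, d), d)
  expect_equal(s$statistic, 0.08)
  expect_equal(s$n_variants, 2L)
  expect_equal(s$n_case_abundant, 1L)

  ctrl_heavy <- variants_from_rates(matrix(rep(c(0.01, 0.01, 0.06, 0.06), 3),
                                           3, byrow = TRUE), d)
  s2 <- burden_statistic(ctrl_heavy, d)
  expect_equal(s2$statistic, -0.15)
  expect_equal(s2$n_case_abundant, 0L)

  empty <- burden_statistic(variants_from_rates(rates, d)[0, ], d)
  expect_equal(empty$statistic, 0)
  expect_equal(empty$n_variants, 0L)
})

test_that("swapping all case/control labels negates the statistic exactly", {
  d <- pool_design(3, 3, 16)
  v <- random_null_variants(20, d, seed = 12)
  swapped <- d
  swapped$label <- ifelse(d$label == "case", "control", "case")
  expect_equal(burden_statistic(v, swapped)$statistic,
               -burden_statistic(v, d)$statistic)
})

test_that("statistic is invariant to variant order and to splitting a pool in half", {
  d <- pool_design(2, 2, 16)
  v <- random_null_variants(15, d, seed = 4)
  expect_equal(burden_statistic(v[sample(15), ], d)$statistic,
               burden_statistic(v, d)$statistic)
  # split the first case pool into two pools of 8 with the same rate
  d_split <- tibble::tibble(
    pool_id = c("case_01a", "case_01b", d$pool_id[-1]),
    label = c("case", "case", d$label[-1]),
    n_individuals = c(8L, 8L, d$n_individuals[-1]),
    alleles = c(16L, 16L, d$alleles[-1])
  )
  v_split <- v
  v_split$case_01a <- v$case_01
  v_split$case_01b <- v$case_01
  expect_equal(burden_statistic(v_split, d_split)$statistic,
               burden_statistic(v, d)$statistic)
})

test_that("label permutations enumerate exhaustively and reproduce from seed", {
  d <- pool_design(3, 3, 16)
  L <- permutation_labels(d, exhaustive = TRUE)
  expect_equal(attr(L, "mode"), "exhaustive")
  expect_equal(ncol(L), 1 + choose(6, 3))                 # 20 arrangements
  expect_equal(anyDuplicated(t(L[, -1])), 0)              # each exactly once
  expect_true(all(colSums(L) == 3))

  big <- pool_design(37, 35, 16)
  L1 <- permutation_labels(big, n_permutations = 50, seed = 7)
  L2 <- permutation_labels(big, n_permutations = 50, seed = 7)
  expect_identical(L1, L2)
  expect_equal(attr(L1, "mode"), "monte_carlo")
  expect_error(permutation_labels(big, exhaustive = TRUE),
               class = "polystrat_config_error")
  expect_error(permutation_labels(pool_design(1, 3, 16)),
               class = "polystrat_data_error")
})

test_that("exhaustive permutation p-values match direct enumeration", {
  d <- pool_design(3, 3, 16)
  # observed labeling gives the strictly largest statistic -> p = 1/20
  rates <- rbind(c(0.9, 0.8, 0.7, 0.1, 0.0, 0.2),
                 c(0.95, 0.85, 0.9, 0.05, 0.1, 0.0))
  oracle <- brute_force_exhaustive_p(rates, d)
  expect_equal(oracle$p, 1 / 20)
  res <- run_polystrat(
    dplyr::mutate(variants_from_rates(rates, d), gene_id = "G1"),
    d, strata = "Overall_All", exhaustive = TRUE
  )
  expect_equal(res$p_uncorrected, oracle$p)

  # random rates: oracle and implementation agree arrangement by arrangement
  withr::with_seed(23, {
    rates2 <- matrix(runif(5 * 6), 5, 6)
  })
  oracle2 <- brute_force_exhaustive_p(rates2, d)
  res2 <- run_polystrat(
    dplyr::mutate(variants_from_rates(rates2, d), gene_id = "G1"),
    d, strata = "Overall_All", exhaustive = TRUE
  )
  expect_equal(res2$statistic, oracle2$observed)
  expect_equal(res2$p_uncorrected, oracle2$p)
})

test_that("permutation p-values use the upper tail with ties counted as extreme", {
  expect_equal(permutation_pvalue(1, rep(1, 10), "monte_carlo"), 1)
  expect_equal(permutation_pvalue(2, c(1, 1, 2, 3), "monte_carlo"), 3 / 5)
  expect_equal(permutation_pvalue(5, 1:10, "exhaustive"), 6 / 10)
  # Monte-Carlo floor: nothing as extreme among B draws -> 1/(B+1)
  expect_equal(permutation_pvalue(10, runif(10000), "monte_carlo"), 1 / 10001)
})

test_that("minP correction is monotone, order-preserving, and exact for one test", {
  withr::with_seed(88, {
    T1 <- matrix(rnorm(501), 1)
    mp1 <- minp_correct(T1, "monte_carlo")
    expect_equal(mp1$p_corrected, mp1$p_uncorrected)

    T10 <- matrix(rnorm(10 * 501), 10)
    mp <- minp_correct(T10, "monte_carlo")
  })
  expect_true(all(mp$p_corrected >= mp$p_uncorrected))
  expect_true(all(mp$p_corrected <= 1))
  o <- order(mp$p_uncorrected)
  expect_true(all(diff(mp$p_corrected[o]) >= 0))
})

test_that("null burden p-values are calibrated independently of gene length", {
  # genes of 8 vs 400 variants; permutation conditions on each gene's own
  # variants, so both should be uniform
  d <- pool_design(10, 10, 16)
  n_small <- 50; n_big <- 25
  v <- withr::with_seed(61, {
    n_v <- c(rep(8, n_small), rep(400, n_big))
    p0 <- rbeta(sum(n_v), 0.5, 4)
    rates <- sapply(d$alleles, function(a) rbinom(sum(n_v), a, p0) / a)
    vv <- variants_from_rates(rates, d)
    vv$gene_id <- rep(sprintf("g%03d", seq_along(n_v)), n_v)
    vv
  })
  res <- run_polystrat(v, d, strata = "Overall_All", n_permutations = 400,
                       seed = 17, exhaustive = FALSE)
  p_small <- res$p_uncorrected[res$n_variants == 8]
  p_big <- res$p_uncorrected[res$n_variants == 400]
  expect_gt(suppressWarnings(stats::ks.test(p_small, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(p_big, "punif"))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(p_small, p_big))$p.value, 0.01)
})

test_that("stratified run tests each gene only in the strata its variants occupy", {
  d <- pool_design(3, 3, 16)
  v <- random_null_variants(30, d, seed = 42)
  v$is_coding <- rep(c(TRUE, FALSE), 15)
  v$gerp <- 0
  v$in_dhs <- FALSE
  v$ref_panel_af <- 0.5
  res <- run_polystrat(v, d, strata = c("Overall_All", "Exon_All", "DHS_All"),
                       n_permutations = 50, seed = 1, exhaustive = FALSE)
  expect_true(all(res$stratum %in% c("Overall_All", "Exon_All")))  # no DHS rows
  ex <- res[res$stratum == "Exon_All", ]
  ov <- res[res$stratum == "Overall_All", ]
  expect_true(all(ex$n_variants <= ov$n_variants[match(ex$unit_id, ov$unit_id)]))
  expect_error(
    run_polystrat(dplyr::mutate(v, in_dhs = FALSE), d, strata = "bogus"),
    class = "polystrat_config_error"
  )
})

test_that("a variant inside two genes' targets contributes to both tests", {
  d <- pool_design(3, 3, 16)
  v <- variants_from_rates(matrix(0.25, 1, 6), d)
  targets <- tibble::tibble(chrom = "chr1", start = c(0L, 5L), end = c(50L, 50L),
                            name = c("GA", "GB"))
  res <- run_polystrat(v, d, targets = targets, strata = "Overall_All",
                       n_permutations = 20, seed = 2, exhaustive = TRUE)
  expect_setequal(res$unit_id, c("GA", "GB"))
  expect_equal(res$statistic[1], res$statistic[2])
})
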