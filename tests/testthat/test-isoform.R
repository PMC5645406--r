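ref_fixture <- function() {
  reference_cohort(
    tibble::tibble(chrom = "chr2", pos = c(100L, 200L, 300L), ref = "A",
                   alt = "G", af = c(0.0033, 0.027, 0.0011)),
    name = "ref", n_individuals = 33370
  )
}

test_that("qualifying filter excludes common, low-confidence and noncoding variants", {
  v <- tibble::tibble(
    chrom = "chr2", pos = c(100L, 200L, 300L, 400L, 500L),
    ref = "A", alt = "G",
    is_coding = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    low_confidence = c(FALSE, FALSE, FALSE, TRUE, FALSE)
  )
  q <- qualifying_variants(v, ref_fixture())
  expect_equal(q$exclusion_reason,
               c(NA, "frequency", NA, "low-confidence", "noncoding"))
  expect_equal(q$qualifying, c(TRUE, FALSE, TRUE, FALSE, FALSE))
  # absent from the reference (pos 400 if it were clean) is kept as rare
  expect_true(is.na(q$ref_af[4]))
})

test_that("variants are assigned to every isoform whose exons contain them", {
  gm <- tibble::tibble(
    chrom = "chr2",
    start = c(90L, 90L, 290L),
    end = c(110L, 110L, 310L),
    gene_id = "G",
    isoform_id = c("iso1", "iso2", "iso2")
  )
  v <- tibble::tibble(chrom = "chr2", pos = c(100L, 300L), ref = "A", alt = "G")
  map <- assign_to_isoforms(gm, v)
  shared <- map$isoform_id[map$pos == 100]
  expect_setequal(shared, c("iso1", "iso2"))       # shared exon: all isoforms
  expect_equal(map$isoform_id[map$pos == 300], "iso2")  # isoform-specific exon
})

test_that("a 17-isoform gene yields 16 degrees of freedom downstream", {
  fix <- simulate_isoform_gene(n_isoforms = 17, variants_per_isoform = 2, seed = 8)
  res <- run_isoform_test(fix$variants, fix$design, fix$gene_model, fix$reference)
  expect_equal(res$genes$n_isoforms, 17L)
  expect_equal(res$genes$df, 16L)
})

test_that("expected counts scale reference frequencies to cohort alleles with a floor", {
  ref <- ref_fixture()
  one <- tibble::tibble(chrom = "chr2", pos = 100L, ref = "A", alt = "G")
  expect_equal(expected_counts(one, ref, 1184), 0.0033 * 1184)  # = 3.907
  expect_equal(expected_counts(one[0, ], ref, 1184), 0)
  absent <- tibble::tibble(chrom = "chr2", pos = 999L, ref = "A", alt = "G")
  expect_equal(expected_counts(absent, ref, 1184), 1184 / (2 * 33370))
  expect_error(expected_counts(one, ref, 0), class = "polystrat_data_error")
})

test_that("isoform chi-square follows the multinomial goodness-of-fit convention", {
  perfect <- tibble::tibble(isoform_id = c("a", "b"), O = c(2, 2), E = c(2, 2))
  expect_equal(isoform_chi2(perfect)$chi2, 0)
  two <- tibble::tibble(isoform_id = c("a", "b"), O = c(4, 0), E = c(2, 2))
  r <- isoform_chi2(two)
  expect_equal(r$chi2, 4)
  expect_equal(r$df, 1L)
  # reorder invariance; an O = E isoform adds df but not chi2
  expect_equal(isoform_chi2(two[2:1, ])$chi2, 4)
  three <- dplyr::bind_rows(two, tibble::tibble(isoform_id = "c", O = 5, E = 5))
  r3 <- isoform_chi2(three)
  expect_equal(r3$chi2, 4)
  expect_equal(r3$df, 2L)
  # fewer than two isoforms with expectation: untestable, not an error
  expect_false(isoform_chi2(two[1, ])$testable)
  expect_false(isoform_chi2(dplyr::mutate(two, E = c(2, 0)))$testable)
})

test_that("chi-square upper tail reproduces the far tail accurately", {
  # printed statistic is rounded to 1 decimal; the printed p must sit
  # inside the tail band implied by that rounding
  p_case <- chi2_upper_tail(82.3, 16)
  expect_lt(chi2_upper_tail(82.35, 16), 6.37e-11)
  expect_gt(chi2_upper_tail(82.25, 16), 6.37e-11)
  expect_lt(abs(p_case / 6.37e-11 - 1), 0.005)
  expect_equal(signif(chi2_upper_tail(10.5, 16), 2), 0.84)
  expect_equal(chi2_upper_tail(0, 7), 1)
  # far tail stays finite and positive
  expect_gt(chi2_upper_tail(1500, 16), 0)
  expect_error(chi2_upper_tail(1, 0), class = "polystrat_data_error")
})

test_that("ratio score and adjusted residuals behave under symmetry and arm exchange", {
  counts <- tibble::tibble(isoform_id = c("a", "b", "c"),
                           O = c(4, 1, 7), E = c(2, 2, 5))
  same <- score_and_residuals(counts, counts)
  expect_equal(same$genes$score, 1)
  expect_equal(same$isoforms$adjusted_residual, rep(1, 3))
  other <- tibble::tibble(isoform_id = c("a", "b", "c"),
                          O = c(2.5, 2, 4), E = c(2, 2, 5))
  ab <- score_and_residuals(counts, other)
  ba <- score_and_residuals(other, counts)
  expect_equal(ab$genes$score, 1 / ba$genes$score)
  expect_equal(ab$genes$chi2_case, ba$genes$chi2_control)
  expect_error(score_and_residuals(counts, other[1:2, ]),
               class = "polystrat_data_error")
})

test_that("adjusted residual and Bonferroni arithmetic match the worked example", {
  # two-isoform fixture engineered to the printed residuals 5.34 and 4.04
  case <- tibble::tibble(isoform_id = c("top", "next"),
                         O = 1 + sqrt(c(5.34, 2)), E = 1)
  ctrl <- tibble::tibble(isoform_id = c("top", "next"),
                         O = 1 + sqrt(c(4.04, 2)), E = 1)
  res <- score_and_residuals(case, ctrl, G = 20000)
  top <- res$isoforms[res$isoforms$isoform_id == "top", ]
  expect_equal(round(top$adjusted_residual, 2), 1.32)
  expect_equal(res$genes$p_corrected,
               min(1, 20000 * res$genes$p_uncorrected))
})

test_that("planted isoform excess is localised by the residual diagnostics", {
  fix <- simulate_isoform_gene(n_isoforms = 6, variants_per_isoform = 3,
                               planted_isoform = 4, excess = 60, seed = 19)
  res <- run_isoform_test(fix$variants, fix$design, fix$gene_model, fix$reference)
  iso <- res$isoforms
  expect_equal(which.max(iso$resid_case), 4L)
  expect_gt(res$genes$score, 1)
  expect_lt(res$genes$p_uncorrected, 1e-4)
  # observed counts recovered from pooled rates match the planted draw
  expect_equal(iso$O_case, fix$case_counts$O)
  expect_equal(iso$E_case, fix$case_counts$E)
})
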