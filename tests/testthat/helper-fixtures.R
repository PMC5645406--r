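# Shared fixture builders. Everything is generated in code; no files.

# Variant table from an explicit rate matrix (variants x pools).
variants_from_rates <- function(rates, design, chrom = "chr1") {
  v <- tibble::tibble(
    chrom = chrom, pos = seq_len(nrow(rates)) * 10L,
    ref = "A", alt = "G"
  )
  colnames(rates) <- design$pool_id
  dplyr::bind_cols(v, tibble::as_tibble(rates))
}

# Random annotated null variants on a small design.
random_null_variants <- function(n, design, seed = NULL) {
  draw <- function() {
    p0 <- stats::rbeta(n, 0.5, 4)
    rates <- sapply(design$alleles, function(a) stats::rbinom(n, a, p0) / a)
    v <- variants_from_rates(rates, design)
    v$gene_id <- paste0("g", seq_len(n) %% 10)
    v
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Independent oracle: point-in-interval by scanning every interval.
brute_force_in_intervals <- function(chrom, pos, bed) {
  vapply(seq_along(pos), function(i) {
    any(bed$chrom == chrom[i] & bed$start < pos[i] & pos[i] <= bed$end)
  }, TRUE)
}

# Independent oracle: exhaustive permutation p-value for the burden
# statistic by direct enumeration with plain arithmetic.
brute_force_exhaustive_p <- function(rates, design) {
  n_pool <- nrow(design)
  n_case <- sum(design$label == "case")
  w <- design$alleles
  stat_for <- function(case_idx) {
    is_case <- seq_len(n_pool) %in% case_idx
    rc <- rates %*% (w * is_case) / sum(w[is_case])
    rw <- rates %*% (w * !is_case) / sum(w[!is_case])
    sum(rc - rw)
  }
  obs <- stat_for(which(design$label == "case"))
  all_stats <- apply(utils::combn(n_pool, n_case), 2, stat_for)
  list(p = mean(all_stats >= obs), observed = obs, all = all_stats)
}

# Independent oracle: hypergeometric upper tail by direct summation of
# the probability mass on the log-choose scale.
brute_force_hyper_tail <- function(K, k, N, n) {
  j <- k:min(K, n)
  sum(exp(lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)))
}
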