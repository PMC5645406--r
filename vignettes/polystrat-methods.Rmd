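---
title: "Annotation-stratified burden testing for pooled sequencing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotation-stratified burden testing for pooled sequencing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polystrat)
```

## The setting: pooled targeted sequencing

In a pooled targeted-sequencing study, DNA from groups of individuals
(here, 16 per pool by default) is combined into bar-coded libraries and
sequenced over a panel of candidate genes. The data that reach the
analyst are not genotypes: for each variant and each pool there is a
single *non-reference allele rate*, the estimated fraction of that
pool's `2 * 16 = 32` chromosomes carrying the alternate allele. The
study design this package defaults to is 37 case pools and 35 control
pools of 16 individuals each (592 cases, 560 controls). Every method in
the package operates on this rate-per-pool representation, and the
permutation machinery treats the **pool as the exchangeable unit** --
individuals cannot be relabelled because they are not observed
individually. This is a design decision forced by the data structure;
its consequence is that the permutation null conditions on the pooling
itself, which is shared by cases and controls and therefore ancillary.

## The stratified burden test

For a set of variants V (a gene's variants, restricted to one
stratum), the burden statistic is

$$ S = \sum_{v \in V} \left( r_{\mathrm{case}}(v) - r_{\mathrm{ctrl}}(v) \right), $$

where each arm rate is the allele-weighted mean over the arm's pools,
$r_{\mathrm{arm}} = \sum_p r_p a_p / \sum_p a_p$ with $a_p = 2 n_p$
alleles in pool $p$. The statistic is deliberately the *unweighted* sum
of rate differences -- no variance standardisation and no
frequency weighting -- so a gene scores highly when many of its
variants are more common in cases, whatever their absolute
frequencies. The test is one-sided (upper tail): only case excess is
of interest.

Variants enter the test through 16 overlapping strata formed by
crossing a functional class with an evolutionary class:

* functional: **Overall** (all variants), **Exon** (coding), **DHS**
  (inside a DNase1-hypersensitivity interval), **Rare**
  (reference-panel allele frequency `< 0.01`, strictly);
* evolutionary: **All**, **Cons** (GERP `> 2`), **Div** (GERP `< -2`),
  **Evo** (either Cons or Div).

All thresholds are strict, so boundary values (GERP exactly 2, panel
AF exactly 0.01) fall outside the special classes; a variant with no
GERP score is neither conserved nor divergent, and a variant absent
from the reference panel is treated as frequency 0, hence rare.
Membership is nested by construction (`Cons` or `Div` implies `Evo`
implies `All`; any special functional class implies `Overall`), which
the test suite verifies as an exact invariant. Stratification
concentrates signal: a gene whose excess is purely regulatory can
reach significance in `DHS_Cons` while staying invisible in a plain
all-variant test.

## Permutation p-values and minP correction

Significance comes from relabelling pools. Column 1 of the label
matrix is the observed case/control assignment; each permutation draws
a uniformly random reassignment preserving the 37/35 arm counts. The
same permutation stream is shared by **every** (gene, stratum) test.
That sharing is what makes the family-wise correction valid: the joint
distribution of all test statistics under the null is sampled
directly, preserving the strong dependence among strata of one gene
(the strata overlap) and among genes (shared pools).

Two conventions matter numerically:

* **Monte-Carlo p-values** use the add-one form
  $p = (\#\{T_b \ge T_{\mathrm{obs}}\} + 1)/(B + 1)$, which can never
  be zero; at the default $B = 10{,}000$ the floor is $10^{-4}$. Ties
  count toward the tail (the conservative choice).
* **Exhaustive mode** enumerates every arrangement exactly once and
  reports $\#\{T \ge T_{\mathrm{obs}}\}/\text{total}$, the identity
  arrangement included, so $p \ge 1/\text{total}$. Exhaustive mode is
  auto-selected when the arrangement count is at most
  `exhaustive_cap` (default 10,000); with 4+4 pools that is
  $\binom{8}{4} = 70$ arrangements, the fixture size used to check
  that Monte-Carlo and exhaustive p-values agree.

Family-wise correction is the single-step minP procedure: for each
permutation $b$, every test's statistic is converted to a pseudo
p-value by ranking within that test's own permutation distribution
(same tie convention), $m(b)$ is the minimum across the family, and
the corrected p of test $t$ is the permutation probability that
$m(b) \le p_t(0)$. This is monotone (corrected $\ge$ uncorrected),
order-preserving, exact for a one-test family, and for independent
tests converges to the Sidak form $1-(1-p)^G$ -- both limits are
exercised in the tests. The default correction family is the full
gene-by-stratum matrix (experiment-wide significance); a per-stratum
family is available via `family = "stratum"`, since either convention
is defensible and the choice is exposed rather than hidden.

Because every gene is ranked against its own permutation
distribution, the test is self-calibrating with respect to gene
length: a 500-variant gene and a 10-variant gene both produce uniform
p-values under the null, which the suite checks explicitly.

Ranking uses exact integer tie counting (`findInterval` on the sorted
null values), not floating-point rank approximations, so pseudo
p-values and reported p-values are consistent to the last ulp.

## Gene-set burden

Sets are pre-filtered for relevance to the sequenced panel with a
one-sided hypergeometric over-representation test against a
genome background of `N = 20,000` genes (configurable): a set is
tested when its enrichment p is strictly below 0.1 **and** it has at
least two targeted member genes (a one-gene set would duplicate the
gene's own test). The exact form of the enrichment filter and the
background size are choices of this package -- the field-standard
over-representation test -- because only the threshold itself is
externally specified. The set statistic is the burden statistic over
the *union* of the member genes' variants: a variant inside two member
genes' targets is counted once, so set statistics add over disjoint
genes but never double-count. Set-level p-values and minP correction
reuse the same permutation stream, with the tested-set collection as
the family.

## The isoform-collapsed reference-cohort test

When a large reference exome cohort (e.g. tens of thousands of
individuals) is available, a gene's coding burden can be tested
against it. Direct frequency comparison would be hopelessly
anti-conservative given the size imbalance, so the test collapses the
gene's qualifying variants onto its transcript isoforms and asks
whether their distribution across isoforms deviates from expectation:

$$ \chi^2 = \sum_{i=1}^{n} \frac{(O_i - E_i)^2}{E_i}, \qquad df = n - 1, $$

with $O_i$ the observed non-reference allele count in isoform $i$
(pooled arm rate times the arm's allele total, a real number) and
$E_i$ the count expected from the reference allele frequencies scaled
to the same allele total. Qualifying variants are coding, have
reference AF at most 0.01, and are not flagged low-confidence; a
variant in an exon shared by several isoforms contributes to each of
them, and the resulting dependence between cells is accepted as part
of the test's design. The `df = n - 1` convention follows the
multinomial goodness-of-fit reading of the statistic.

The same statistic is computed for the control arm, and the
**score** is the ratio $\chi^2_{\mathrm{case}} / \chi^2_{\mathrm{ctrl}}$:
a deviation shared by both arms (capture artefacts, panel differences)
cancels, while case-specific burden inflates the ratio. Per-isoform
residuals $(O_i - E_i)^2/E_i$ localise the burden, and the *adjusted
residual* (case residual / control residual) corrects each isoform for
how far the control data already sit from the reference. Significance
is the chi-square upper tail of the case statistic with Bonferroni
correction over `G = 20,000` genes.

Numerical details: variants absent from the reference take the floor
frequency $1/(2 n_{\mathrm{ref}})$ (one allele in the reference);
isoforms whose expected count falls below `e_min = 1e-8` are dropped
from both arms symmetrically with the df reduced; a gene with fewer
than two includable isoforms is reported untestable rather than
erring; a zero control chi-square yields an infinite score sentinel.
Whether observed counts should be integers (genotyped) or reals
(pooled rates times alleles) is ambiguous in principle; this package
accepts real-valued counts because that is what pooled data provide.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions so that every
statistical claim in the package is testable without any external
data. Defaults are the reference study geometry and marginals: 37 + 35 pools of 16; population
allele frequencies from Beta(0.2, 4), a rare-skewed distribution
under which roughly half of variants have AF below 0.01; annotation
marginals of 16% coding (51% of coding synonymous), 36% DHS, 80%
conserved-or-divergent. Where a value had to be chosen without
external guidance: constrained variants split 70/30 between conserved
and divergent (only the class label, not the magnitude, matters
downstream); GERP magnitudes are drawn uniformly from (2.2, 6) for
constrained and (-1.9, 1.9) for unconstrained variants; the
reference-panel AF mirrors the population control-arm frequency;
sequencing noise is a truncated Gaussian on the rate scale with sd
0.01, a simple stand-in for shallow per-individual coverage.

Effects are planted on the odds scale: a planted gene at odds ratio
OR and control AF $p_0$ gives its variants the case frequency solving
$\mathrm{odds}(p_1) = \mathrm{OR} \cdot \mathrm{odds}(p_0)$, so e.g.
OR 2.4 at $p_0 = 0.022$ yields $p_1 = 0.0512$, a per-variant rate
difference of about 0.029; the generator's mean shift is tested
against this closed form. An additive risk-difference mode is
available as an option. Pool allele counts are binomial
($2 \times$ pool size draws at the arm frequency), which reproduces
the genotype lattice $\{0, 0.5, 1\}$ in the degenerate
one-individual-pool case.

`simulate_isoform_gene()` builds the isoform test's fixture with
isoform-specific (disjoint) exons so that per-isoform observed counts
are exactly multinomial at the reference expectations -- the sharpest
possible null for checking the $\chi^2_{n-1}$ calibration -- and
plants integer allele excess into one isoform for recovery tests.
Pool rates are produced by sampling allele slots without replacement,
so the counts implied by the rates round-trip exactly through the
pooled-rate arithmetic.

What the generator does **not** emulate: linkage disequilibrium
between variants (all variants are independent), population
stratification, batch effects between arms, caller disagreement, or
depth-dependent error. Passing tests therefore demonstrate the
statistical machinery is correct under the stated model, not that
real-data artefacts (notably LD-inflated burden signals, which real
analyses must check separately) are handled.

## Problem sizes used by the test suite

The suite's heavier checks run at sizes chosen to make their
statistical assertions sharp while keeping the default test run
short: null calibration uses 2,000 genes at the full pool geometry
with 2,000 permutations (rejection rate at $\alpha = 0.05$ expected in
[0.04, 0.06], about a 2-sigma band); power replicates use 200 cohorts
at the full geometry with $B = 199$; Monte-Carlo/exhaustive agreement
uses 4+4 pools where enumeration is exact; the isoform null uses
10,000 multinomial draws at 5 isoforms. A 2-sigma per-gene band is
expected to cover about 95% of independent comparisons, so the
agreement check asserts at-least-90% coverage rather than demanding
every gene fall inside it.

## Known limitations

* Pool-level permutation cannot separate within-pool from
  between-pool variance; a pool with aberrant depth affects all its
  variants coherently and the test inherits that coupling.
* The burden statistic's lack of variance weighting means a single
  common variant can dominate a gene's statistic; the `Rare` stratum
  is the built-in counterweight, not a per-variant weight.
* The isoform test conditions on the isoform structure as given;
  annotation differences between the cohort's and the reference's
  transcript models propagate directly into $O/E$.
* Monte-Carlo corrected p-values inherit the $1/(B+1)$ floor; claims
  below the floor require raising `n_permutations` (cost is linear
  in B).
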