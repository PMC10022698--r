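---
title: "Methods: forensic InDel panel statistics and population structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: forensic InDel panel statistics and population structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelkit)
```

## Scope and model

`indelkit` characterizes panels of biallelic insertion/deletion (InDel)
markers of the kind used in forensic identification: each locus has an
insertion (I) and a deletion (D) allele, and an individual's genotype is
summarized as the insertion dosage 0/1/2. The package covers the full
statistical workflow of a forensic population study on such a panel:
per-locus efficiency parameters and their panel-wide combination,
equilibrium testing, and multi-population structure inference. It ships with
the published per-locus summary table of a 57-locus autosomal panel typed in
262 individuals from the Hubei Tujia group, which it can invert back to
exact genotype counts (see below), so the entire per-locus analysis is
reproducible from the printed table alone.

## Reconstructing genotype counts from published summaries

Published tables report the insertion frequency $\hat p$ and observed
heterozygosity $H_o$ to four decimals, not the genotype counts
$(n_{II}, n_{ID}, n_{DD})$. For a sample of $n$ diploids the printed values
are $\mathrm{round}(a/2n, 4)$ and $\mathrm{round}(n_{ID}/n, 4)$ with
$a = 2 n_{II} + n_{ID}$ the insertion-allele count. With $n = 262$,
neighbouring counts differ by $1/524 \approx 0.0019 > 10^{-4}$, so rounding
to four decimals is injective and inverts exactly:

* $n_{ID} = \mathrm{round}(H_o \cdot n)$, $a = \mathrm{round}(\hat p \cdot 2n)$
  (half away from zero, matching report rounding);
* if $a - n_{ID}$ is odd — impossible for genuine data, reachable only
  through a rounding boundary — $a$ is nudged by $\pm 1$, choosing the value
  closer to the printed frequency and decrementing on ties;
* $n_{II} = (a - n_{ID})/2$, $n_{DD} = n - n_{ID} - n_{II}$; a negative
  count raises an error naming the inconsistent summary.

On the bundled 57-locus table no parity repair is ever needed, and
recomputing every statistic from the reconstructed counts reproduces every
printed column at four decimals (asserted in the test suite).

`build_published_fixture()` lays the reconstructed counts out as a
262 × 57 dosage matrix, one locus at a time (insertion homozygotes first,
then heterozygotes, then deletion homozygotes). Single-locus statistics on
this matrix are exact; the *joint* arrangement across loci is deliberately
artificial, so the fixture must never be used to study two-locus structure —
the package validates linkage disequilibrium on synthetic data with known
haplotype truth instead. An optional seeded per-locus shuffle
(`shuffle_seed`) is available for permutation-style checks; it leaves all
single-locus counts unchanged.

## Per-locus forensic parameters

For counts $(n_{II}, n_{ID}, n_{DD})$, $p = (2n_{II}+n_{ID})/2n$, $q = 1-p$:

* **Observed heterozygosity** $H_o = n_{ID}/n$.
* **Expected heterozygosity**: Nei's unbiased estimator
  $H_e = \frac{2n}{2n-1}\,(1 - p^2 - q^2)$. The bias correction matters at
  this precision: at the panel's most diverse locus the biased form gives
  0.4999 where the published value is 0.5009.
* **Polymorphism information content** (Botstein), biallelic form
  $PIC = 1 - (p^2+q^2) - 2p^2q^2$, maximal at $0.375$ for $p = 0.5$.
* **Match probability** $PM = \sum_g \hat f_g^2$ over the three *observed*
  genotype frequencies — not the Hardy–Weinberg expectations. The observed
  form is what standard forensic software reports, and it is the form that
  reproduces the published values exactly.
* **Power of discrimination** $PD = 1 - PM$.
* **Probability of paternity exclusion**: the trio form driven by
  heterozygosity, $PE = h^2(1 - 2hH^2)$ with $h = H_o$, $H = 1 - h$. The
  duo form is not implemented; the trio form reproduces every published
  cell.

### Combined panel values

$CPD = 1 - \prod_\ell PM_\ell$ and $CPE = 1 - \prod_\ell (1 - PE_\ell)$.
For 57 loci $\prod PM \approx 3\times10^{-24}$, far below the resolution of
`1 - x` in double precision, so `combined_statistics()` accumulates both
products in log space (`sum(log10(pm))`, `sum(log1p(-pe))`) and renders the
CPD decimal string from its *complement* by integer arithmetic
(`format_unity_complement()`): the complement is representable even though
the CPD itself rounds to 1. The rendered 29-decimal string, not the double,
is the reportable quantity.

```{r combined}
fixture <- build_published_fixture()
summaries <- locus_summary_table(fixture)
combined_statistics(summaries)
```

Report tables round half away from zero to 4 decimals
(`round_half_up()`), matching the convention of published forensic tables;
base R's round-half-to-even would disagree on boundary cells.

## Hardy–Weinberg testing

`hwe_exact_pvalue()` is the conditional exact test: given the allele
counts, the probability of each parity-consistent heterozygote count $h$ is

$$P(h \mid n, n_I) = \frac{n!}{n_{II}!\,n_{ID}!\,n_{DD}!}\;
2^{h}\;\frac{n_I!\,n_D!}{(2n)!},$$

and the p-value sums all outcomes with probability not exceeding the
observed one (probability ordering, ties included — the two-sided
convention of Wigginton's widely used implementation). Enumeration is full,
in log-gamma space, normalized so the distribution sums to one; a relative
tolerance of $10^{-12}$ guards tie detection against floating-point noise.
The test suite checks it against a plain-factorial oracle over every
configuration with $n \le 10$ and hundreds of random ones up to $n = 30$.

`hwe_mc_pvalue()` is the permutation counterpart (alleles shuffled into
random pairings, same probability-ordering statistic) with the
$(b+1)/(B+1)$ correction so the estimate is never zero; it is seeded and
reproducible. The published per-locus p-values are consistent with a
Monte-Carlo version of the exact test, so both are provided; the package
reports the enumeration test by default because at $n = 262$ it is both
exact and instant. The panel-level claim — no deviation after Bonferroni
correction at $0.05/57 = 0.00087719$ — is recomputed in the acceptance
suite (minimum exact p across the panel ≈ 0.022).

## Linkage disequilibrium

`em_haplotype_freqs()` estimates two-locus haplotype frequencies from a
3 × 3 joint dosage table by gene counting (EM): only the double
heterozygote is phase-ambiguous, and each E-step splits it between the
cis (AB/ab) and trans (Ab/aB) resolutions in proportion to the current
estimates. Initialization is at linkage equilibrium; convergence is
declared when the log-likelihood gains less than `tol` (default
$10^{-10}$) within `max_iter` (default 1000), otherwise the result is
flagged unconverged. The EM solution is checked in the tests against a
brute-force grid search over the single free phase parameter.
`ld_r2()` then reports $D = p_{AB} - p_A p_B$ and
$r^2 = D^2 / (p_A(1-p_A)\,p_B(1-p_B))$; it refuses monomorphic margins,
where $r^2$ is undefined.

## Population distances

* **Nei's DA** (biallelic form):
  $D_A(x,y) = \frac{1}{L}\sum_\ell \left(1 - \sqrt{x_\ell y_\ell} -
  \sqrt{(1-x_\ell)(1-y_\ell)}\right)$, in $[0,1]$, zero iff the frequency
  profiles coincide.
* **Weir–Cockerham θ** from genotypes: the standard variance-component
  estimator ($a$, $b$, $c$ components per locus; multi-locus θ as the ratio
  of summed components). Loci monomorphic in both populations are excluded
  with a warning; negative estimates are reported as computed (an optional
  clamp exists only for heatmap export in the Hudson matrix variant).
* **Hudson FST** from frequencies alone, with the sample-size bias
  correction, for settings where only reference-panel frequencies are
  available; the pairwise matrix combines loci as a ratio of averages.

The original study obtained its FST values from AMOVA-based software whose
exact option set is unpublished; Weir–Cockerham θ estimates the same
quantity for biallelic diploid data and is the form implemented here. No
numeric reconciliation against the study's FST heatmap is attempted (the
heatmap prints no values).

## Structure inference

* **Neighbor joining** uses the Saitou–Nei algorithm (via `ape::nj`) behind
  `neighbor_joining()`; on additive inputs the reconstruction is exact
  (verified to $10^{-9}$ over random trees with 4–10 leaves). Negative
  branch lengths on noisy inputs are retained with a warning rather than
  zeroed. `write_newick()` serializes with branch lengths and quotes labels
  containing metacharacters; round trips are tested against an independent
  parser.
* **PCA** of the population × locus frequency matrix: column-centered,
  unscaled (frequencies share a scale), by SVD. Explained fractions are
  $\lambda_i / \sum \lambda$; component signs are fixed by forcing each
  component's largest-magnitude loading positive, making output fully
  deterministic. A constant matrix raises an error rather than returning a
  zero decomposition.
* **Admixture model**: individual $i$'s two allele copies at locus $j$ each
  come from ancestral component $k$ with probability $q_{ik}$ and are
  insertions with probability $f_{kj}$, giving the binomial log-likelihood
  $\sum_{ij} g_{ij}\log(\textstyle\sum_k q_{ik}f_{kj}) +
  (2-g_{ij})\log(1-\sum_k q_{ik}f_{kj})$. `admixture_em()` maximizes it by
  plain EM — adequate at the panel sizes this package targets and with a
  simple monotone-likelihood contract (asserted on every trace), in place
  of the quasi-Newton acceleration production admixture software uses for
  genome-scale data. Defaults: 5 random restarts (seeds `seed + 0:4`), best
  final likelihood kept; `f` clipped to $[10^{-6}, 1-10^{-6}]$; `q` rows
  renormalized each step. Components are identifiable only up to
  permutation; `align_components()` resolves label switching by exhaustive
  search over the $k!$ permutations maximizing summed column correlation
  (practical to $k = 8$).

## Synthetic data: what it does and does not emulate

The generators provide data with exactly the structure the estimators
assume, under fixed seeds (each generator restores the caller's RNG state):

* `sample_hwe_population()` — independent Binomial(2, p) dosages: the
  Hardy–Weinberg, linkage-equilibrium null.
* `sample_two_locus_ld()` — diploids paired from haplotype draws at given
  haplotype frequencies: known-truth LD.
* `sample_admixed_population()` — the admixture generative model itself.
* `build_reference_panel()` — populations drifting from a common founder by
  Balding–Nichols sampling, $p_\text{pop} \sim
  \mathrm{Beta}(p\frac{1-c}{c}, (1-p)\frac{1-c}{c})$, with the drift
  parameter $c$ an FST-like divergence. Drawn frequencies are kept off the
  boundary ($[10^{-4}, 1-10^{-4}]$) so downstream estimators stay defined.

These panels emulate the *statistical* structure of a target-plus-references
design (drift-scaled divergence, admixed individuals, two-locus LD) but not
the features of real population data: no linkage maps, no ascertainment
bias in locus choice, no mutation, no real allele-frequency correlations
among populations. Passing recovery tests on them demonstrates estimator
correctness under the model, not robustness to real-data violations of it.

In recovery tests the two-population ancestry panels use inter-population
frequency differentials of at least 0.4 (sources at 0.05–0.3 versus
0.7–0.95) over 100 loci — the regime of ancestry-informative markers, which
is what unambiguous individual assignment requires; at smaller differentials
the maximum-likelihood ancestry of an unadmixed individual is genuinely
interior, not a deficiency of the EM.

## Problem sizes and numerical choices

The bundled analyses and tests run at desk scale, chosen so the full suite
completes in well under a minute of compute per module: exact HWE
enumeration over all configurations to $n = 10$ plus 200 random ones to
$n = 30$; LD recovery at $n = 10^4$ diploids; NJ recovery over 100 random
trees; admixture recovery with 80–100 individuals × 100 loci and 3
restarts; drift monotonicity over 5 levels with 200-diploid populations.
Tolerances: $10^{-9}$ for tree-metric recovery, 3 binomial/delta-method
standard errors for stochastic recoveries, exact printed precision (4
decimals) for every published table comparison.

## Known limitations

* The reconstruction inverts 4-decimal summaries only where rounding is
  injective (guaranteed at $n = 262$; at much larger $n$ ambiguity is
  possible and the property tests would flag it).
* The admixture EM is not accelerated; at thousands of individuals ×
  genome-scale loci it would be slow (by design out of scope).
* The exact HWE enumeration is for biallelic loci only.
* The study's multi-population figures rest on reference-panel frequencies
  that are not redistributable; those analyses are therefore validated on
  synthetic panels, and `read_frequency_table()` accepts user-supplied
  tables for full reproduction.
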