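#' Insertion-allele frequency from genotype counts
#'
#' @param counts [genotype_counts()].
#' @return `(2 n_II + n_ID) / (2n)`.
#' @export
insertion_frequency <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$n == 0L) stop("no typed individuals", call. = FALSE)
  (2 * counts$n_ii + counts$n_id) / (2 * counts$n)
}

#' Observed heterozygosity
#'
#' Proportion of heterozygous individuals, `n_ID / n`.
#'
#' @param counts [genotype_counts()].
#' @return value in `[0, 1]`.
#' @export
observed_heterozygosity <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$n == 0L) stop("no typed individuals", call. = FALSE)
  counts$n_id / counts$n
}

#' Unbiased expected heterozygosity (gene diversity)
#'
#' Nei's sample-size-corrected estimator
#' `He = 2n/(2n - 1) * (1 - p^2 - q^2)`, the form forensic population
#' reports print. Undefined below two individuals.
#'
#' @param counts [genotype_counts()].
#' @return value in `[0, n/(2n-1)]`.
#' @export
unbiased_expected_heterozygosity <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  n <- counts$n
  if (n < 2L) stop("unbiased He needs n >= 2", call. = FALSE)
  p <- insertion_frequency(counts)
  q <- 1 - p
  2 * n / (2 * n - 1) * (1 - p^2 - q^2)
}

#' Polymorphism information content of a biallelic marker
#'
#' Botstein's PIC reduced to two alleles:
#' `PIC = 1 - (p^2 + q^2) - 2 p^2 q^2`, maximal at 0.375 when p = 0.5.
#'
#' @param p insertion-allele frequency in `[0, 1]`.
#' @return value in `[0, 0.375]`.
#' @export
pic_biallelic <- function(p) {
  stopifnot(all(p >= 0), all(p <= 1))
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Probability of match
#'
#' Probability that two individuals drawn at random from the sample share a
#' genotype: the sum of squared *observed* genotype frequencies (not the
#' Hardy-Weinberg expectations).
#'
#' @param counts [genotype_counts()].
#' @return value in `(0, 1]`.
#' @export
match_probability <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$n == 0L) stop("no typed individuals", call. = FALSE)
  sum((c(counts$n_ii, counts$n_id, counts$n_dd) / counts$n)^2)
}

#' Power of discrimination
#'
#' Complement of the match probability, `PD = 1 - PM`.
#'
#' @param counts [genotype_counts()].
#' @return value in `[0, 1)`.
#' @export
power_of_discrimination <- function(counts) {
  1 - match_probability(counts)
}

#' Probability of paternity exclusion
#'
#' Trio exclusion probability driven by heterozygosity:
#' `PE = h^2 (1 - 2 h H^2)` with `h` the observed heterozygosity and
#' `H = 1 - h`.
#'
#' @param ho observed heterozygosity in `[0, 1]`.
#' @return value in `[0, 1]`; 0 at `ho = 0`, 1 at `ho = 1`.
#' @export
power_of_exclusion <- function(ho) {
  stopifnot(all(ho >= 0), all(ho <= 1))
  H <- 1 - ho
  ho^2 * (1 - 2 * ho * H^2)
}

#' Per-locus forensic summary table
#'
#' One row per locus with every standard forensic efficiency parameter:
#' allele frequencies, Ho, unbiased He, PIC, PM, PD, PE, and the exact
#' Hardy-Weinberg p-value. Monomorphic loci are flagged: their PIC and PD
#' are 0 and He/PM degenerate accordingly.
#'
#' @param x [genotype_matrix()].
#' @param hwe one of `"enumeration"` (default, exact) or `"monte_carlo"`.
#' @param n_draws,seed Monte Carlo settings, used only when
#'   `hwe = "monte_carlo"`.
#' @return data.frame with columns `locus`, `f_ins`, `f_del`, `he`, `ho`,
#'   `pic`, `pm`, `pd`, `pe`, `p_hwe`, `monomorphic`, at full precision
#'   (round for reporting with [round_half_up()]).
#' @export
locus_summary_table <- function(x, hwe = c("enumeration", "monte_carlo"),
                                n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(x, "genotype_matrix"))
  hwe <- match.arg(hwe)
  rows <- lapply(seq_len(ncol(x)), function(j) {
    cnt <- tabulate_counts(x, j)
    p <- insertion_frequency(cnt)
    ho <- observed_heterozygosity(cnt)
    p_hwe <- if (hwe == "enumeration") {
      hwe_exact_pvalue(cnt)
    } else {
      hwe_mc_pvalue(cnt, n_draws = n_draws, seed = seed + j)
    }
    data.frame(locus = colnames(x)[j],
               f_ins = p, f_del = 1 - p,
               he = unbiased_expected_heterozygosity(cnt),
               ho = ho,
               pic = pic_biallelic(p),
               pm = match_probability(cnt),
               pd = power_of_discrimination(cnt),
               pe = power_of_exclusion(ho),
               p_hwe = p_hwe,
               monomorphic = (p == 0 || p == 1))
  })
  do.call(rbind, rows)
}

#' Combined forensic statistics of a marker panel
#'
#' Panel-level combined power of discrimination `CPD = 1 - prod(PM)` and
#' combined exclusion probability `CPE = 1 - prod(1 - PE)`. For dozens of
#' loci `prod(PM)` is far below the double-precision resolution of `1 - x`,
#' so both products are accumulated in log space and the CPD is additionally
#' rendered as a fixed-point decimal string from its complement (see
#' [format_unity_complement()]).
#'
#' @param summaries data.frame from [locus_summary_table()] (columns `pm`
#'   and `pe` required).
#' @param render_digits decimal places for the rendered CPD string.
#' @return list of class `combined_summary`: `cpd`, `cpe` (doubles),
#'   `pm_product` and `log10_pm_product` (the CPD complement),
#'   `log10_cpe_complement`, and `cpd_rendered` (character).
#' @export
combined_statistics <- function(summaries, render_digits = 29L) {
  stopifnot(is.data.frame(summaries), all(c("pm", "pe") %in% names(summaries)),
            nrow(summaries) >= 1L)
  pm <- summaries$pm
  pe <- summaries$pe
  if (any(pm <= 0)) stop("PM of 0 has no log; check input summaries", call. = FALSE)
  if (any(pm > 1) || any(pe < 0) || any(pe > 1)) {
    stop("pm and pe must lie in (0,1] and [0,1]", call. = FALSE)
  }
  log10_pm <- sum(log10(pm))
  pm_product <- 10^log10_pm
  log1p_cpe <- sum(log1p(-pe))
  structure(list(
    cpd = 1 - pm_product,
    cpe = -expm1(log1p_cpe),
    pm_product = pm_product,
    log10_pm_product = log10_pm,
    log10_cpe_complement = log1p_cpe / log(10),
    cpd_rendered = format_unity_complement(pm_product, render_digits),
    n_loci = nrow(summaries)
  ), class = "combined_summary")
}

#' @export
print.combined_summary <- function(x, ...) {
  cat("<combined_summary> ", x$n_loci, " loci\n",
      "  CPD = ", x$cpd_rendered, "  (complement ",
      format(x$pm_product, digits = 6), ")\n",
      "  CPE = ", format(x$cpe, digits = 15), "\n", sep = "")
  invisible(x)
}

#' Write the forensic report files for a genotype panel
#'
#' Emits the per-locus summary as CSV (published-table column order, values
#' rounded to `digits` decimals), the combined statistics as JSON (rendered
#' strings plus log-complements at full precision), and the Hardy-Weinberg
#' results with a Bonferroni significance flag.
#'
#' @param x [genotype_matrix()].
#' @param out_dir output directory, created if needed.
#' @param alpha panel-wise significance level for the Bonferroni flag.
#' @param digits report rounding (default 4).
#' @return invisibly, a list with the summary data.frame and combined list.
#' @export
write_forensic_report <- function(x, out_dir, alpha = 0.05, digits = 4L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  smry <- locus_summary_table(x)
  comb <- combined_statistics(smry)
  thr <- bonferroni_threshold(alpha, nrow(smry))

  report <- data.frame(
    locus = smry$locus,
    f_ins = round_half_up(smry$f_ins, digits),
    f_del = round_half_up(smry$f_del, digits),
    he = round_half_up(smry$he, digits),
    ho = round_half_up(smry$ho, digits),
    pic = round_half_up(smry$pic, digits),
    pm = round_half_up(smry$pm, digits),
    pd = round_half_up(smry$pd, digits),
    pe = round_half_up(smry$pe, digits),
    p_hwe = round_half_up(smry$p_hwe, digits)
  )
  utils::write.csv(report, file.path(out_dir, "locus_summary.csv"),
                   row.names = FALSE)

  hwe <- data.frame(locus = smry$locus, p_hwe = smry$p_hwe,
                    bonferroni_threshold = thr,
                    significant = smry$p_hwe < thr)
  utils::write.csv(hwe, file.path(out_dir, "hwe_tests.csv"), row.names = FALSE)

  jsonlite::write_json(
    list(n_loci = comb$n_loci,
         cpd = comb$cpd_rendered,
         cpd_complement = comb$pm_product,
         log10_pm_product = comb$log10_pm_product,
         cpe = format(comb$cpe, digits = 15),
         log10_cpe_complement = comb$log10_cpe_complement),
    file.path(out_dir, "combined_statistics.json"),
    auto_unbox = TRUE, digits = NA)

  invisible(list(summary = smry, combined = comb, hwe = hwe))
}
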