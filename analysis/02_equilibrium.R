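#!/usr/bin/env Rscript
# Hardy-Weinberg and linkage-disequilibrium checks.
#
# Part 1: exact (full-enumeration) Hardy-Weinberg tests at all 57 loci of
# the rebuilt study matrix, with the Bonferroni-corrected panel threshold.
# Part 2: the EM r^2 estimator is exercised on synthetic two-locus data at
# known haplotype frequencies -- the rebuilt matrix itself carries no real
# two-locus structure (loci are reconstructed independently), so LD is
# validated on data whose truth is known.

suppressPackageStartupMessages(library(indelkit))
dir.create("results", showWarnings = FALSE)

fixture <- build_published_fixture()
smry <- locus_summary_table(fixture)
threshold <- bonferroni_threshold(0.05, nrow(smry))

hwe <- data.frame(locus = smry$locus,
                  p_exact = round_half_up(smry$p_hwe, 4),
                  significant_after_bonferroni = smry$p_hwe < threshold)
write.csv(hwe, "results/hwe_exact.csv", row.names = FALSE)

cat("Exact HWE tests at", nrow(hwe), "loci\n")
cat("  Bonferroni threshold 0.05/", nrow(hwe), " = ",
    format(round_half_up(threshold, 8), nsmall = 8), "\n", sep = "")
cat("  minimum p =", format(min(smry$p_hwe), digits = 4), "at",
    smry$locus[which.min(smry$p_hwe)], "\n")
cat("  loci significant after correction:",
    sum(hwe$significant_after_bonferroni), "\n\n")

# LD validation at known truth
scenarios <- list(
  complete_ld = c(0.5, 0, 0, 0.5),
  strong_ld = c(0.4, 0.1, 0.1, 0.4),
  moderate_ld = c(0.4, 0.1, 0.2, 0.3),
  equilibrium = c(0.25, 0.25, 0.25, 0.25)
)
n <- 10000L
ld <- do.call(rbind, lapply(names(scenarios), function(name) {
  hap <- scenarios[[name]]
  pA <- hap[1] + hap[2]
  pB <- hap[1] + hap[3]
  d <- hap[1] - pA * pB
  r2_true <- d^2 / (pA * (1 - pA) * pB * (1 - pB))
  est <- ld_r2(sample_two_locus_ld(hap, n, seed = 101), tol = 1e-12)
  data.frame(scenario = name, n = n, r2_true = r2_true,
             r2_estimated = est$r2, em_iterations = est$em_iterations)
}))
write.csv(ld, "results/ld_synthetic.csv", row.names = FALSE)
cat("EM r^2 recovery on synthetic two-locus data (n = 10000):\n")
print(ld, row.names = FALSE, digits = 4)
cat("\nWrote results/hwe_exact.csv and results/ld_synthetic.csv\n")
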