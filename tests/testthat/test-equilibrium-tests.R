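test_that("exact HWE p-values match hand enumerations", {
  # two heterozygotes, no homozygotes: P(h=2) = 2/3 (mode), p = 2/3 + 1/3
  expect_equal(hwe_exact_pvalue(genotype_counts(0, 2, 0)), 1)
  # one of each homozygote: P(h=0) = 1/3, the least likely outcome
  expect_equal(hwe_exact_pvalue(genotype_counts(1, 0, 1)), 1 / 3)
  # monomorphic: single possible outcome
  expect_equal(hwe_exact_pvalue(genotype_counts(9, 0, 0)), 1)
})

test_that("enumeration agrees with the factorial oracle over all configurations", {
  # exhaustive for small n, random configurations up to n = 30
  configs <- list()
  for (n in 1:8) {
    for (n_ii in 0:n) for (n_id in 0:(n - n_ii)) {
      configs[[length(configs) + 1L]] <- c(n_ii, n_id, n - n_ii - n_id)
    }
  }
  set.seed(3)
  for (rep in 1:150) {
    n <- sample(9:30, 1)
    n_ii <- sample(0:n, 1)
    n_id <- sample(0:(n - n_ii), 1)
    configs[[length(configs) + 1L]] <- c(n_ii, n_id, n - n_ii - n_id)
  }
  for (cfg in configs) {
    got <- hwe_exact_pvalue(genotype_counts(cfg[1], cfg[2], cfg[3]))
    want <- oracle_hwe_pvalue(cfg[1], cfg[2], cfg[3])
    expect_equal(got, want, tolerance = 1e-10,
                 info = paste(cfg, collapse = "/"))
    # the enumerated null distribution is a proper distribution
    n_ins <- 2 * cfg[1] + cfg[2]
    n <- sum(cfg)
    if (n_ins > 0 && n_ins < 2 * n) {
      expect_equal(sum(oracle_hwe_probs(n, n_ins)), 1, tolerance = 1e-12)
    }
  }
})

test_that("Monte Carlo HWE is seeded, reproducible, and converges to the exact value", {
  cnt <- genotype_counts(73, 118, 71)
  a <- hwe_mc_pvalue(cnt, n_draws = 2000, seed = 99)
  b <- hwe_mc_pvalue(cnt, n_draws = 2000, seed = 99)
  expect_identical(a$p, b$p)

  exact <- hwe_exact_pvalue(cnt)
  mc <- hwe_mc_pvalue(cnt, n_draws = 10000, seed = 1)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(mc$p - exact), 3 * se + 1 / 10001)

  # single draw with the (b+1)/(B+1) correction can only be 1/2 or 1
  p1 <- hwe_mc_pvalue(cnt, n_draws = 1, seed = 5)$p
  expect_true(p1 %in% c(0.5, 1))
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(round_half_up(bonferroni_threshold(0.05, 57), 8), 0.00087719)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.01, 2), 0.005)
  expect_error(bonferroni_threshold(0.05, 0), ">= 1")
})

test_that("EM haplotype frequencies: unambiguous tables are direct tallies", {
  # no double heterozygotes -> phase fully observed
  cnt <- matrix(0, 3, 3)
  cnt[3, 3] <- 10  # AB/AB
  cnt[1, 1] <- 20  # ab/ab
  cnt[3, 2] <- 6   # AB/Ab
  cnt[2, 1] <- 4   # Ab/ab
  em <- em_haplotype_freqs(cnt)
  total <- 2 * sum(cnt)
  expect_equal(unname(em$freqs),
               c(26, 10, 0, 44) / total, tolerance = 1e-9)
  expect_true(em$converged)

  # 100 individuals all AB/ab double hets plus anchoring homozygotes
  cnt2 <- matrix(0, 3, 3)
  cnt2[2, 2] <- 100
  em2 <- em_haplotype_freqs(cnt2)
  # symmetric start stays symmetric: cis and trans resolutions equally likely
  expect_equal(sum(em2$freqs), 1)
  cnt2[3, 3] <- 1  # one AB/AB homozygote tips the balance toward cis
  em3 <- em_haplotype_freqs(cnt2)
  expect_gt(em3$freqs["AB"], 0.45)
  expect_gt(em3$freqs["ab"], 0.45)
})

test_that("EM matches the brute-force likelihood maximizer on random tables", {
  set.seed(21)
  for (rep in 1:8) {
    cnt <- matrix(rpois(9, 8), 3, 3)
    em <- em_haplotype_freqs(cnt)
    expect_true(all(diff(em$loglik_trace) >= -1e-9))
    expect_equal(sum(em$freqs), 1, tolerance = 1e-12)
    grid <- oracle_em_grid(cnt)
    expect_equal(oracle_two_locus_loglik(cnt, em$freqs), grid$ll,
                 tolerance = 1e-6)
    expect_equal(unname(em$freqs), unname(grid$p), tolerance = 1e-3)
  }
})

test_that("EM marginals reproduce the allele frequencies", {
  set.seed(8)
  for (rep in 1:10) {
    cnt <- matrix(rpois(9, 5), 3, 3)
    if (sum(cnt) == 0) next
    em <- em_haplotype_freqs(cnt)
    pA <- sum(cnt * matrix(rep(0:2, 3), 3, 3)) / (2 * sum(cnt))
    pB <- sum(cnt * matrix(rep(0:2, each = 3), 3, 3)) / (2 * sum(cnt))
    expect_equal(unname(em$freqs["AB"] + em$freqs["Ab"]), pA, tolerance = 1e-9)
    expect_equal(unname(em$freqs["AB"] + em$freqs["aB"]), pB, tolerance = 1e-9)
  }
})

test_that("r2 is 1 under complete LD, 0 when D = 0, and small for independent loci", {
  complete <- sample_two_locus_ld(c(0.5, 0, 0, 0.5), 500, seed = 2)
  expect_equal(ld_r2(complete)$r2, 1, tolerance = 1e-9)

  # D = 0 by construction: counts exactly at linkage equilibrium
  eq <- matrix(0, 3, 3)
  for (i in 0:2) for (j in 0:2) {
    eq[i + 1, j + 1] <- 400 * dbinom(i, 2, 0.5) * dbinom(j, 2, 0.5)
  }
  expect_equal(ld_r2(eq)$r2, 0, tolerance = 1e-12)

  indep <- sample_two_locus_ld(c(0.25, 0.25, 0.25, 0.25), 10000, seed = 4)
  expect_lt(ld_r2(indep)$r2, 0.01)

  mono <- matrix(0, 3, 3)
  mono[3, 2] <- 5
  expect_error(ld_r2(mono), "monomorphic")
})

test_that("r2 is invariant under allele relabeling at either locus", {
  set.seed(15)
  cnt <- matrix(rpois(9, 6) + 1, 3, 3)
  base <- ld_r2(cnt)$r2
  expect_equal(ld_r2(cnt[3:1, ])$r2, base, tolerance = 1e-9)
  expect_equal(ld_r2(cnt[, 3:1])$r2, base, tolerance = 1e-9)
  expect_equal(ld_r2(cnt[3:1, 3:1])$r2, base, tolerance = 1e-9)
})

test_that("pairwise r2 matrix is symmetric with NA for monomorphic loci", {
  gm <- sample_hwe_population(c(0.5, 0.3, 0), 60, seed = 9)
  m <- ld_r2_matrix(gm)
  expect_true(isSymmetric(m))
  expect_true(all(is.na(m[, 3])))
  expect_false(is.na(m[1, 2]))
})
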