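# Independent oracles used across the suite. These deliberately take the
# slow/naive route (plain factorials, grid search, exhaustive enumeration)
# so they share no code with the implementation they check.

# Levene conditional distribution of the heterozygote count, via plain
# factorials (exact in double precision for n <= 30).
oracle_hwe_probs <- function(n, n_ins) {
  n_del <- 2 * n - n_ins
  h_values <- Filter(function(h) {
    (n_ins - h) >= 0 && (n_del - h) >= 0 &&
      (n_ins - h) %% 2 == 0 && (n_del - h) %% 2 == 0
  }, 0:min(n_ins, n_del))
  probs <- vapply(h_values, function(h) {
    nii <- (n_ins - h) / 2
    ndd <- (n_del - h) / 2
    factorial(n) / (factorial(nii) * factorial(h) * factorial(ndd)) *
      2^h * factorial(n_ins) * factorial(n_del) / factorial(2 * n)
  }, numeric(1))
  setNames(probs, h_values)
}

oracle_hwe_pvalue <- function(n_ii, n_id, n_dd) {
  n <- n_ii + n_id + n_dd
  n_ins <- 2 * n_ii + n_id
  if (n_ins == 0 || n_ins == 2 * n) return(1)
  probs <- oracle_hwe_probs(n, n_ins)
  p_obs <- probs[[as.character(n_id)]]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-9)]))
}

# Multinomial log-likelihood of a 3x3 joint dosage table under haplotype
# frequencies (AB, Ab, aB, ab).
oracle_two_locus_loglik <- function(cnt, p) {
  pr <- matrix(0, 3, 3)
  pr[3, 3] <- p[1]^2; pr[3, 2] <- 2 * p[1] * p[2]; pr[3, 1] <- p[2]^2
  pr[2, 3] <- 2 * p[1] * p[3]; pr[2, 1] <- 2 * p[2] * p[4]
  pr[1, 3] <- p[3]^2; pr[1, 2] <- 2 * p[3] * p[4]; pr[1, 1] <- p[4]^2
  pr[2, 2] <- 2 * (p[1] * p[4] + p[2] * p[3])
  sum(cnt[cnt > 0] * log(pr[cnt > 0]))
}

# Brute-force ML haplotype frequencies: the only free quantity given the
# allele-count margins is the number of double heterozygotes resolved as
# cis (AB/ab); scan it on a fine grid.
oracle_em_grid <- function(cnt, grid_n = 20001) {
  cnt <- as.matrix(cnt)
  n <- sum(cnt)
  known <- c(
    AB = 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3],
    Ab = 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1],
    aB = 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3],
    ab = 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
  )
  n11 <- cnt[2, 2]
  ts <- seq(0, 1, length.out = grid_n)
  best <- NULL
  for (t in ts) {
    p <- (known + n11 * c(t, 1 - t, 1 - t, t)) / (2 * n)
    ll <- oracle_two_locus_loglik(cnt, pmax(p, 1e-300))
    if (is.null(best) || ll > best$ll) best <- list(ll = ll, p = p)
  }
  best
}

# Weir & Cockerham (1984) theta for one biallelic locus and two populations,
# written out directly from the published component formulas.
oracle_wc_theta_one_locus <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a / (a + b + cc)
}

# all permutations of 1..k, built independently of the package's generator
oracle_perms <- function(k) {
  if (k == 1) return(list(1L))
  grid <- do.call(expand.grid, rep(list(seq_len(k)), k))
  keep <- apply(grid, 1, function(row) length(unique(row)) == k)
  lapply(which(keep), function(i) as.integer(grid[i, ]))
}

published_summaries <- function() {
  read.csv(published_summary_path())
}
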