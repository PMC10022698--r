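# Conditional distribution of the heterozygote count given allele counts:
# log P(n_ID = h | n, n_I) for every parity-consistent h. Returned as a
# normalized probability vector named by h.
.hwe_het_distribution <- function(n, n_ins) {
  n_del <- 2 * n - n_ins
  n_rare <- min(n_ins, n_del)
  h <- seq(n_rare %% 2, n_rare, by = 2)
  hom_rare <- (n_rare - h) / 2
  hom_common <- n - h - hom_rare
  logp <- lgamma(n + 1) - lgamma(hom_rare + 1) - lgamma(h + 1) -
    lgamma(hom_common + 1) + h * log(2) +
    lgamma(n_ins + 1) + lgamma(n_del + 1) - lgamma(2 * n + 1)
  p <- exp(logp - max(logp))
  stats::setNames(p / sum(p), h)
}

#' Exact Hardy-Weinberg test for a biallelic locus
#'
#' Full-enumeration conditional exact test: given the observed allele
#' counts, every parity-consistent heterozygote count is enumerated under
#' the Hardy-Weinberg null and the p-value is the total probability of
#' outcomes no more likely than the observed one (probability ordering,
#' ties included).
#'
#' @param counts [genotype_counts()].
#' @return p-value in `(0, 1]`.
#' @export
#' @examples
#' hwe_exact_pvalue(genotype_counts(1, 0, 1))  # 1/3
hwe_exact_pvalue <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  if (counts$n == 0L) stop("no typed individuals", call. = FALSE)
  n_ins <- 2 * counts$n_ii + counts$n_id
  if (n_ins == 0L || n_ins == 2L * counts$n) return(1)
  dist <- .hwe_het_distribution(counts$n, n_ins)
  p_obs <- dist[[as.character(counts$n_id)]]
  # relative tolerance so that outcomes tied with the observed probability
  # are counted despite floating-point noise
  min(1, sum(dist[dist <= p_obs * (1 + 1e-12)]))
}

#' Monte Carlo Hardy-Weinberg test
#'
#' Permutation version of [hwe_exact_pvalue()]: the 2n observed alleles are
#' repeatedly shuffled into random diploid pairings, and the p-value is the
#' proportion of pairings whose conditional probability does not exceed the
#' observed one, with the `(b + 1) / (B + 1)` correction so the estimate is
#' never zero.
#'
#' @param counts [genotype_counts()].
#' @param n_draws number of shuffles.
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @return list of class `hwe_result`: `p`, `method`, `n_draws`, `seed`.
#' @export
hwe_mc_pvalue <- function(counts, n_draws = 10000L, seed = 1L) {
  stopifnot(inherits(counts, "genotype_counts"), n_draws >= 1L)
  if (counts$n == 0L) stop("no typed individuals", call. = FALSE)
  n <- counts$n
  n_ins <- 2 * counts$n_ii + counts$n_id
  if (n_ins == 0L || n_ins == 2L * n) {
    return(structure(list(p = 1, method = "monte_carlo",
                          n_draws = as.integer(n_draws),
                          seed = as.integer(seed)),
                     class = "hwe_result"))
  }
  dist <- .hwe_het_distribution(n, n_ins)
  p_obs <- dist[[as.character(counts$n_id)]]
  alleles <- rep(c(1L, 0L), c(n_ins, 2L * n - n_ins))
  hits <- with_seed(seed, {
    vapply(seq_len(n_draws), function(b) {
      a <- sample(alleles)
      h <- sum(a[seq(1L, 2L * n, by = 2L)] != a[seq(2L, 2L * n, by = 2L)])
      dist[[as.character(h)]] <= p_obs * (1 + 1e-12)
    }, logical(1))
  })
  structure(list(p = (sum(hits) + 1) / (n_draws + 1), method = "monte_carlo",
                 n_draws = as.integer(n_draws), seed = as.integer(seed)),
            class = "hwe_result")
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha panel-wise level, in `(0, 1)`.
#' @param m number of tests, `>= 1`.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' EM estimation of two-locus haplotype frequencies from unphased genotypes
#'
#' Maximum-likelihood haplotype frequencies for two biallelic loci from a
#' 3x3 table of joint insertion dosages. Only the double heterozygote is
#' phase-ambiguous; the EM splits it between the AB/ab and Ab/aB resolutions
#' in proportion to the current frequency estimates (Hill's gene-counting
#' algorithm). The log-likelihood is non-decreasing across iterations.
#'
#' @param joint_counts 3x3 matrix of counts; rows = insertion dosage at the
#'   first locus (0, 1, 2), columns = dosage at the second locus.
#' @param tol convergence threshold on the log-likelihood increase.
#' @param max_iter iteration cap; if reached the result is flagged
#'   `converged = FALSE`.
#' @return list: `freqs` (named `AB`, `Ab`, `aB`, `ab`, summing to 1, with
#'   `A`/`B` the insertion alleles), `loglik`, `loglik_trace`, `iterations`,
#'   `converged`.
#' @export
em_haplotype_freqs <- function(joint_counts, tol = 1e-10, max_iter = 1000L) {
  cnt <- as.matrix(joint_counts)
  stopifnot(all(dim(cnt) == c(3L, 3L)), all(cnt >= 0), sum(cnt) >= 1)
  n <- sum(cnt)
  # known haplotype tallies from the eight phase-unambiguous cells;
  # cnt[i+1, j+1] holds dosage (i, j)
  d1 <- matrix(rep(0:2, 3), 3, 3)          # dosage at locus 1
  d2 <- t(d1)                               # dosage at locus 2
  # direct unambiguous contributions
  hap_known <- function() {
    AB <- 2 * cnt[3, 3] + cnt[3, 2] + cnt[2, 3]
    Ab <- 2 * cnt[3, 1] + cnt[3, 2] + cnt[2, 1]
    aB <- 2 * cnt[1, 3] + cnt[1, 2] + cnt[2, 3]
    ab <- 2 * cnt[1, 1] + cnt[1, 2] + cnt[2, 1]
    c(AB = AB, Ab = Ab, aB = aB, ab = ab)
  }
  known <- hap_known()
  n11 <- cnt[2, 2]

  loglik_of <- function(p) {
    # multinomial log-likelihood over the nine genotype cells
    pr <- matrix(0, 3, 3)
    pr[3, 3] <- p["AB"]^2; pr[1, 1] <- p["ab"]^2
    pr[3, 1] <- p["Ab"]^2; pr[1, 3] <- p["aB"]^2
    pr[3, 2] <- 2 * p["AB"] * p["Ab"]; pr[1, 2] <- 2 * p["aB"] * p["ab"]
    pr[2, 3] <- 2 * p["AB"] * p["aB"]; pr[2, 1] <- 2 * p["Ab"] * p["ab"]
    pr[2, 2] <- 2 * (p["AB"] * p["ab"] + p["Ab"] * p["aB"])
    sum(cnt[cnt > 0] * log(pr[cnt > 0]))
  }

  # initialize at linkage equilibrium from the marginal allele frequencies
  pA <- sum(cnt * d1) / (2 * n)
  pB <- sum(cnt * d2) / (2 * n)
  p <- c(AB = pA * pB, Ab = pA * (1 - pB), aB = (1 - pA) * pB,
         ab = (1 - pA) * (1 - pB))
  p <- pmax(p, .Machine$double.xmin)
  trace <- loglik_of(p)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    cis <- p["AB"] * p["ab"]
    trans <- p["Ab"] * p["aB"]
    w <- if (cis + trans > 0) cis / (cis + trans) else 0.5
    new <- known + n11 * c(w, 1 - w, 1 - w, w)
    p <- new / (2 * n)
    ll <- loglik_of(pmax(p, .Machine$double.xmin))
    trace <- c(trace, ll)
    if (abs(ll - trace[iter]) < tol) {
      converged <- TRUE
      break
    }
  }
  list(freqs = p, loglik = trace[length(trace)], loglik_trace = trace,
       iterations = iter, converged = converged)
}

#' Pairwise linkage disequilibrium r-squared from unphased genotypes
#'
#' Estimates haplotype frequencies with [em_haplotype_freqs()] and returns
#' the squared allelic correlation
#' `r^2 = D^2 / (pA (1-pA) pB (1-pB))` with `D = p_AB - pA pB`.
#'
#' @param joint_counts 3x3 joint dosage count table (see
#'   [em_haplotype_freqs()]).
#' @param ... passed to [em_haplotype_freqs()].
#' @return list of class `ld_result`: `r2`, `d`, `haplotype_freqs`,
#'   `em_iterations`, `converged`.
#' @export
ld_r2 <- function(joint_counts, ...) {
  cnt <- as.matrix(joint_counts)
  n <- sum(cnt)
  pA <- sum(cnt * matrix(rep(0:2, 3), 3, 3)) / (2 * n)
  pB <- sum(cnt * matrix(rep(0:2, each = 3), 3, 3)) / (2 * n)
  if (pA %in% c(0, 1) || pB %in% c(0, 1)) {
    stop("r^2 undefined: a locus is monomorphic in this sample", call. = FALSE)
  }
  em <- em_haplotype_freqs(cnt, ...)
  d <- unname(em$freqs["AB"] - pA * pB)
  structure(list(r2 = d^2 / (pA * (1 - pA) * pB * (1 - pB)), d = d,
                 haplotype_freqs = em$freqs, em_iterations = em$iterations,
                 converged = em$converged),
            class = "ld_result")
}

#' Pairwise r-squared matrix for a genotype panel
#'
#' Applies [ld_r2()] to every locus pair of a genotype matrix, skipping
#' pairs involving a monomorphic locus (entries left `NA`).
#'
#' @param x [genotype_matrix()].
#' @param ... passed to [em_haplotype_freqs()].
#' @return symmetric numeric matrix of r-squared values, `NA` diagonal.
#' @export
ld_r2_matrix <- function(x, ...) {
  stopifnot(inherits(x, "genotype_matrix"))
  L <- ncol(x)
  out <- matrix(NA_real_, L, L, dimnames = list(colnames(x), colnames(x)))
  for (i in seq_len(L - 1L)) {
    for (j in seq.int(i + 1L, L)) {
      ok <- !is.na(x[, i]) & !is.na(x[, j])
      tab <- table(factor(x[ok, i], levels = 0:2),
                   factor(x[ok, j], levels = 0:2))
      res <- tryCatch(ld_r2(tab, ...), error = function(e) NULL)
      if (!is.null(res)) out[i, j] <- out[j, i] <- res$r2
    }
  }
  out
}
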