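#' Sample a population in Hardy-Weinberg equilibrium
#'
#' Each locus genotype is an independent Binomial(2, p) insertion dosage —
#' the null model every Hardy-Weinberg test in this package assumes.
#'
#' @param freqs per-locus insertion-allele frequencies.
#' @param n number of diploid individuals.
#' @param seed RNG seed; the caller's RNG state is untouched.
#' @param locus_ids,prefix optional locus ids / sample-id prefix.
#' @return [genotype_matrix()], `n` x `length(freqs)`.
#' @export
sample_hwe_population <- function(freqs, n, seed = 1L, locus_ids = NULL,
                                  prefix = "S") {
  stopifnot(all(freqs >= 0), all(freqs <= 1), n >= 1)
  if (is.null(locus_ids)) {
    locus_ids <- names(freqs)
    if (is.null(locus_ids)) locus_ids <- paste0("L", seq_along(freqs))
  }
  dosage <- with_seed(seed, {
    vapply(freqs, function(p) stats::rbinom(n, 2L, p), integer(n))
  })
  if (n == 1L) dosage <- matrix(dosage, nrow = 1L)
  genotype_matrix(dosage, sprintf("%s%03d", prefix, seq_len(n)), locus_ids)
}

#' Sample genotypes under an admixture model
#'
#' Each of an individual's two allele copies independently picks an
#' ancestral component from its ancestry vector and then an allele from
#' that component's frequency — the generative model [admixture_em()] fits.
#'
#' @param q individuals x K ancestry matrix; rows must sum to 1.
#' @param f K x loci matrix of ancestral insertion frequencies.
#' @param seed RNG seed.
#' @param locus_ids,prefix optional labels.
#' @return [genotype_matrix()].
#' @export
sample_admixed_population <- function(q, f, seed = 1L, locus_ids = NULL,
                                      prefix = "S") {
  q <- as.matrix(q)
  f <- as.matrix(f)
  if (ncol(q) != nrow(f)) {
    stop("q has ", ncol(q), " components but f has ", nrow(f), call. = FALSE)
  }
  if (max(abs(rowSums(q) - 1)) > 1e-9) {
    stop("each row of q must sum to 1", call. = FALSE)
  }
  n <- nrow(q)
  L <- ncol(f)
  if (is.null(locus_ids)) locus_ids <- colnames(f)
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(L))
  dosage <- with_seed(seed, {
    d <- matrix(0L, n, L)
    for (copy in 1:2) {
      # component of origin for this copy, per individual x locus
      comp <- vapply(seq_len(n), function(i) {
        sample.int(ncol(q), L, replace = TRUE, prob = q[i, ])
      }, integer(L))
      comp <- t(comp)
      pij <- matrix(f[cbind(as.vector(comp), rep(seq_len(L), each = n))], n, L)
      d <- d + (matrix(stats::runif(n * L), n, L) < pij)
    }
    d
  })
  genotype_matrix(dosage, sprintf("%s%03d", prefix, seq_len(n)), locus_ids)
}

#' Sample a two-locus genotype table with known linkage disequilibrium
#'
#' Draws `2n` haplotypes from the given four haplotype frequencies, pairs
#' them into diploids, and tabulates joint insertion dosages — the input
#' format of [em_haplotype_freqs()] and [ld_r2()].
#'
#' @param haplotype_freqs length-4 numeric in order `AB, Ab, aB, ab`
#'   (`A`/`B` the insertion alleles), summing to 1.
#' @param n number of diploid individuals.
#' @param seed RNG seed.
#' @return 3x3 count matrix, rows = dosage at the first locus (0,1,2),
#'   columns = dosage at the second.
#' @export
sample_two_locus_ld <- function(haplotype_freqs, n, seed = 1L) {
  stopifnot(length(haplotype_freqs) == 4L, all(haplotype_freqs >= 0),
            abs(sum(haplotype_freqs) - 1) < 1e-9, n >= 1)
  # haplotype -> (allele at locus 1, allele at locus 2)
  a1 <- c(1L, 1L, 0L, 0L)
  a2 <- c(1L, 0L, 1L, 0L)
  with_seed(seed, {
    hap <- sample.int(4L, 2L * n, replace = TRUE, prob = haplotype_freqs)
    first <- hap[seq(1L, 2L * n, by = 2L)]
    second <- hap[seq(2L, 2L * n, by = 2L)]
    d1 <- a1[first] + a1[second]
    d2 <- a2[first] + a2[second]
    as.matrix(table(factor(d1, levels = 0:2), factor(d2, levels = 0:2)))
  })
}

#' Path of the bundled published per-locus summary file
#'
#' 57 autosomal InDel loci with their published insertion-allele frequency,
#' observed heterozygosity and forensic parameters (n = 262 diploid
#' individuals).
#'
#' @return file path of the bundled CSV.
#' @export
published_summary_path <- function() {
  system.file("extdata", "tujia_published_summaries.csv", package = "indelkit",
              mustWork = TRUE)
}

#' Rebuild the study genotype matrix from the bundled published summaries
#'
#' Reconstructs exact per-locus genotype counts from the bundled summary
#' file via [reconstruct_counts_from_summary()] and lays them out as a
#' 262 x 57 genotype matrix: for each locus the insertion homozygotes come
#' first, then the heterozygotes, then the deletion homozygotes. Every
#' *single-locus* statistic on this matrix reproduces the published values;
#' the multi-locus arrangement is deliberately artificial (loci are filled
#' independently), so two-locus structure in this fixture carries no
#' information about the real population.
#'
#' @param shuffle_seed if non-`NULL`, each locus column is independently
#'   permuted with this seed (single-locus statistics are unchanged).
#' @return [genotype_matrix()], 262 x 57.
#' @export
build_published_fixture <- function(shuffle_seed = NULL) {
  tab <- utils::read.csv(published_summary_path())
  n <- 262L
  dosage <- matrix(NA_integer_, n, nrow(tab))
  for (j in seq_len(nrow(tab))) {
    cnt <- tryCatch(
      reconstruct_counts_from_summary(tab$f_ins[j], tab$ho[j], n),
      error = function(e) {
        stop("reconstruction failed for locus ", tab$locus[j], ": ",
             conditionMessage(e), call. = FALSE)
      })
    dosage[, j] <- rep(c(2L, 1L, 0L), c(cnt$n_ii, cnt$n_id, cnt$n_dd))
  }
  if (!is.null(shuffle_seed)) {
    dosage <- with_seed(shuffle_seed, {
      apply(dosage, 2, sample)
    })
  }
  genotype_matrix(dosage, sprintf("TJ%03d", seq_len(n)), tab$locus)
}

#' Simulate a diverged reference panel by Balding-Nichols drift
#'
#' Stand-in for a set of reference populations descended from a common
#' founder: each population's per-locus frequency is drawn from the
#' Balding-Nichols distribution `Beta(p (1-c)/c, (1-p)(1-c)/c)` around the
#' founder frequency `p`, where the drift parameter `c` plays the role of
#' an FST to the founder (`c = 0` means no drift: frequencies equal the
#' founder's). Genotypes are then sampled in Hardy-Weinberg proportions at
#' the drifted frequencies.
#'
#' @param founder_freqs per-locus founder insertion frequencies.
#' @param populations data.frame with columns `id`, `size` (diploids) and
#'   `drift` (`c` in `[0, 1)`).
#' @param seed RNG seed.
#' @return list: `frequencies` ([frequency_table()] of the drifted
#'   population frequencies) and `genotypes` (named list of
#'   [genotype_matrix()]).
#' @export
build_reference_panel <- function(founder_freqs, populations, seed = 1L) {
  stopifnot(is.data.frame(populations),
            all(c("id", "size", "drift") %in% names(populations)),
            all(populations$size >= 1), all(populations$drift >= 0),
            all(populations$drift < 1),
            all(founder_freqs >= 0), all(founder_freqs <= 1))
  L <- length(founder_freqs)
  locus_ids <- names(founder_freqs)
  if (is.null(locus_ids)) locus_ids <- paste0("L", seq_len(L))
  n_pop <- nrow(populations)
  freqs <- with_seed(seed, {
    m <- matrix(0, n_pop, L)
    for (i in seq_len(n_pop)) {
      c_i <- populations$drift[i]
      m[i, ] <- if (c_i == 0) {
        founder_freqs
      } else {
        shape <- (1 - c_i) / c_i
        drawn <- stats::rbeta(L, founder_freqs * shape,
                              (1 - founder_freqs) * shape)
        # keep loci segregating so downstream estimators stay defined
        pmin(pmax(drawn, 1e-4), 1 - 1e-4)
      }
    }
    m
  })
  genotypes <- lapply(seq_len(n_pop), function(i) {
    sample_hwe_population(freqs[i, ], populations$size[i],
                          seed = seed + 1000L + i, locus_ids = locus_ids,
                          prefix = paste0(populations$id[i], "_"))
  })
  names(genotypes) <- populations$id
  list(frequencies = frequency_table(freqs, populations$id, locus_ids,
                                     populations$size),
       genotypes = genotypes)
}
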