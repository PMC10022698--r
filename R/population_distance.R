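#' Construct a pairwise population distance matrix
#'
#' @param values symmetric numeric matrix with zero diagonal.
#' @param population_ids row/column labels.
#' @param metric_name name of the distance ("nei_da", "fst", ...).
#' @return object of class `distance_matrix`.
#' @export
distance_matrix <- function(values, population_ids, metric_name) {
  values <- as.matrix(values)
  population_ids <- as.character(population_ids)
  stopifnot(nrow(values) == ncol(values),
            nrow(values) == length(population_ids))
  if (max(abs(values - t(values))) > 1e-12 || any(abs(diag(values)) > 1e-12)) {
    stop("distance matrix must be symmetric with zero diagonal", call. = FALSE)
  }
  dimnames(values) <- list(population_ids, population_ids)
  structure(values, metric_name = metric_name,
            class = c("distance_matrix", "matrix", "array"))
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat("<distance_matrix> ", attr(x, "metric_name"), ", ", nrow(x),
      " populations\n", sep = "")
  print(round(unclass(x), 4))
  invisible(x)
}

#' Nei's DA genetic distance between populations
#'
#' For biallelic loci,
#' `DA(x, y) = mean over loci of 1 - (sqrt(px py) + sqrt(qx qy))`,
#' the complement of the mean geometric overlap of allele frequencies. Lies
#' in `[0, 1]`, zero for identical frequency profiles.
#'
#' @param table [frequency_table()] with at least two populations.
#' @return [distance_matrix()] with `metric_name = "nei_da"`.
#' @export
nei_da_matrix <- function(table) {
  stopifnot(inherits(table, "frequency_table"))
  if (nrow(table) < 2L || ncol(table) < 1L) {
    stop("need >= 2 populations and >= 1 locus", call. = FALSE)
  }
  r <- nrow(table)
  out <- matrix(0, r, r)
  for (i in seq_len(r - 1L)) {
    for (j in seq.int(i + 1L, r)) {
      x <- table[i, ]
      y <- table[j, ]
      out[i, j] <- out[j, i] <-
        mean(1 - (sqrt(x * y) + sqrt((1 - x) * (1 - y))))
    }
  }
  distance_matrix(out, rownames(table), "nei_da")
}

# Weir-Cockerham (1984) variance components a, b, c for one biallelic locus
# across r populations; inputs are per-population sample sizes, insertion
# frequencies and observed heterozygote proportions.
.wc_components <- function(n, p, h) {
  r <- length(n)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

#' Weir-Cockerham FST between two populations from genotype counts
#'
#' Multi-locus theta: the ratio of the summed among-population variance
#' component to the summed total, over all loci polymorphic in at least one
#' population. Loci monomorphic for the same allele in both populations
#' carry no information and are dropped with a warning. Negative estimates
#' are reported as computed.
#'
#' @param counts_a,counts_b lists of [genotype_counts()] over the same loci,
#'   in the same order; each population needs `n >= 2` at every locus.
#' @return theta (double) with attribute `per_locus`, a data.frame of the
#'   per-locus a/b/c variance components.
#' @export
fst_weir_cockerham <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == length(counts_b), length(counts_a) >= 1L)
  comp <- t(vapply(seq_along(counts_a), function(l) {
    ca <- counts_a[[l]]
    cb <- counts_b[[l]]
    stopifnot(inherits(ca, "genotype_counts"), inherits(cb, "genotype_counts"))
    if (ca$n < 2L || cb$n < 2L) {
      stop("Weir-Cockerham theta needs n >= 2 per population", call. = FALSE)
    }
    .wc_components(c(ca$n, cb$n),
                   c(insertion_frequency(ca), insertion_frequency(cb)),
                   c(observed_heterozygosity(ca), observed_heterozygosity(cb)))
  }, numeric(3)))
  informative <- rowSums(abs(comp)) > 0
  if (!all(informative)) {
    warning(sum(!informative),
            " locus/loci monomorphic in both populations excluded")
  }
  if (!any(informative)) {
    stop("no informative loci: all monomorphic in both populations",
         call. = FALSE)
  }
  theta <- sum(comp[informative, "a"]) / sum(comp[informative, ])
  attr(theta, "per_locus") <- data.frame(comp)
  theta
}

#' Hudson FST from allele frequencies alone
#'
#' Bias-corrected Hudson estimator for one biallelic locus, usable when only
#' population frequencies are available (e.g. external reference panels):
#' numerator `(p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)`, denominator
#' `p1(1-p2) + p2(1-p1)`.
#'
#' @param p1,p2 insertion-allele frequencies.
#' @param n1,n2 numbers of sampled allele copies (twice the diploid sample
#'   size), `>= 2`.
#' @return FST estimate (can be slightly negative by sampling noise).
#' @export
fst_hudson <- function(p1, n1, p2, n2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1, n1 >= 2, n2 >= 2)
  denom <- p1 * (1 - p2) + p2 * (1 - p1)
  if (denom == 0) {
    stop("FST undefined: both populations monomorphic for the same allele",
         call. = FALSE)
  }
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  num / denom
}

#' Pairwise FST matrix from a frequency table
#'
#' Multi-locus Hudson FST ("ratio of averages": numerators and denominators
#' summed over loci before dividing) for every population pair.
#'
#' @param table [frequency_table()].
#' @param clamp_negative set small negative estimates to zero (useful for
#'   heatmap export); default `FALSE`.
#' @return [distance_matrix()] with `metric_name = "fst_hudson"`.
#' @export
fst_hudson_matrix <- function(table, clamp_negative = FALSE) {
  stopifnot(inherits(table, "frequency_table"))
  sizes <- 2L * attr(table, "sample_sizes")
  r <- nrow(table)
  out <- matrix(0, r, r)
  for (i in seq_len(r - 1L)) {
    for (j in seq.int(i + 1L, r)) {
      p1 <- table[i, ]
      p2 <- table[j, ]
      num <- (p1 - p2)^2 - p1 * (1 - p1) / (sizes[i] - 1) -
        p2 * (1 - p2) / (sizes[j] - 1)
      den <- p1 * (1 - p2) + p2 * (1 - p1)
      keep <- den > 0
      if (!any(keep)) {
        stop("populations '", rownames(table)[i], "' and '",
             rownames(table)[j], "' share no polymorphic locus", call. = FALSE)
      }
      est <- sum(num[keep]) / sum(den[keep])
      out[i, j] <- out[j, i] <- if (clamp_negative) max(est, 0) else est
    }
  }
  distance_matrix(out, rownames(table), "fst_hudson")
}

#' Write a distance matrix in PHYLIP square format
#'
#' @param dm [distance_matrix()].
#' @param path output file.
#' @export
write_distance_phylip <- function(dm, path) {
  stopifnot(inherits(dm, "distance_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(dm)), con)
  for (i in seq_len(nrow(dm))) {
    writeLines(paste(c(formatC(rownames(dm)[i], width = -10),
                       sprintf("%.6f", dm[i, ])), collapse = "  "), con)
  }
  invisible(path)
}
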