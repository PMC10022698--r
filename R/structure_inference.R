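#' Neighbor-joining tree from a population distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) on a pairwise distance
#' matrix. For additive (tree-metric) inputs the reconstruction is exact:
#' path lengths on the returned tree reproduce the input distances.
#' Negative branch lengths, which can arise on non-additive inputs, are
#' retained and reported with a warning.
#'
#' @param dm [distance_matrix()] (or any symmetric matrix with labels) over
#'   at least three populations.
#' @return unrooted `phylo` tree with the populations as tips.
#' @export
neighbor_joining <- function(dm) {
  m <- unclass(as.matrix(dm))
  if (nrow(m) < 3L) stop("neighbor joining needs >= 3 populations", call. = FALSE)
  tree <- ape::nj(m)
  if (any(tree$edge.length < 0)) {
    warning("tree contains negative branch lengths (non-additive input)")
  }
  tree
}

# quote a label for Newick if it contains metacharacters; single quotes
# inside labels are doubled per the format
.newick_label <- function(label) {
  if (grepl("[][(){},;:='\\s]", label, perl = TRUE)) {
    paste0("'", gsub("'", "''", label), "'")
  } else {
    label
  }
}

#' Write a tree as a Newick file
#'
#' Serializes a `phylo` tree with branch lengths, quoting any label that
#' contains Newick metacharacters or whitespace.
#'
#' @param tree `phylo` object.
#' @param path output file.
#' @param digits significant digits for branch lengths.
#' @return invisibly, the Newick string.
#' @export
write_newick <- function(tree, path, digits = 10L) {
  stopifnot(inherits(tree, "phylo"))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  fmt_len <- function(edge_row) {
    if (is.null(tree$edge.length)) "" else
      paste0(":", format(tree$edge.length[edge_row], digits = digits))
  }
  render <- function(node) {
    rows <- children[[as.character(node)]]
    if (is.null(rows)) return(.newick_label(tree$tip.label[node]))
    inner <- vapply(rows, function(r) {
      paste0(render(tree$edge[r, 2]), fmt_len(r))
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  newick <- paste0(render(root), ";")
  writeLines(newick, path)
  invisible(newick)
}

#' PCA of a population x locus allele-frequency matrix
#'
#' Singular-value decomposition of the column-centered (unscaled) frequency
#' matrix, the standard ordination for population-level allele frequencies.
#' Component signs are fixed by forcing the largest-magnitude loading of
#' each component positive, so results are fully deterministic.
#'
#' @param table [frequency_table()] or plain numeric matrix, populations in
#'   rows.
#' @param n_components number of components to return; defaults to the full
#'   rank `min(populations - 1, loci)`.
#' @return list of class `pca_result`: `scores` (populations x components),
#'   `explained_fraction` (per retained component, of the *total* variance),
#'   `loadings`, `center`.
#' @export
pca_frequencies <- function(table, n_components = NULL) {
  m <- unclass(as.matrix(table))
  if (nrow(m) < 2L) stop("PCA needs >= 2 populations", call. = FALSE)
  full_rank <- min(nrow(m) - 1L, ncol(m))
  if (is.null(n_components)) n_components <- full_rank
  if (n_components < 1L || n_components > full_rank) {
    stop("n_components must lie in [1, ", full_rank, "]", call. = FALSE)
  }
  centered <- scale(m, center = TRUE, scale = FALSE)
  total_var <- sum(centered^2)
  if (total_var < .Machine$double.eps * length(centered)) {
    stop("frequency matrix is constant across populations: no variance to decompose",
         call. = FALSE)
  }
  sv <- svd(centered)
  keep <- seq_len(n_components)
  flip <- vapply(keep, function(k) {
    v <- sv$v[, k]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], n_components),
                  2, flip, `*`)
  loadings <- sweep(sv$v[, keep, drop = FALSE], 2, flip, `*`)
  dimnames(scores) <- list(rownames(m), paste0("PC", keep))
  dimnames(loadings) <- list(colnames(m), paste0("PC", keep))
  structure(list(scores = scores,
                 explained_fraction = sv$d[keep]^2 / sum(sv$d^2),
                 loadings = loadings,
                 center = attr(centered, "scaled:center")),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result> ", nrow(x$scores), " populations, ",
      ncol(x$scores), " components\n  explained: ",
      paste(sprintf("%.1f%%", 100 * x$explained_fraction), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# one EM pass of the admixture model; returns updated q, f and the
# log-likelihood of the *incoming* parameters
.admixture_em_step <- function(g, q, f, eps = 1e-6) {
  n <- nrow(g)
  k <- ncol(q)
  miss <- is.na(g)
  g0 <- ifelse(miss, 0, g)
  p <- q %*% f                     # expected insertion frequency per (i, j)
  p <- pmin(pmax(p, eps), 1 - eps)
  ll <- sum((g0 * log(p) + (2 - g0) * log(1 - p))[!miss])
  a_tot <- matrix(0, n, k)         # expected insertion copies from each component
  b_tot <- matrix(0, n, k)         # expected deletion copies
  f_num <- matrix(0, k, ncol(g))
  f_den <- matrix(0, k, ncol(g))
  for (comp in seq_len(k)) {
    num1 <- outer(q[, comp], f[comp, ])        # q_ik f_kj
    num0 <- outer(q[, comp], 1 - f[comp, ])
    a <- ifelse(miss, 0, g0 * num1 / p)
    b <- ifelse(miss, 0, (2 - g0) * num0 / (1 - p))
    a_tot[, comp] <- rowSums(a)
    b_tot[, comp] <- rowSums(b)
    f_num[comp, ] <- colSums(a)
    f_den[comp, ] <- colSums(a + b)
  }
  copies <- 2 * rowSums(!miss)
  q_new <- (a_tot + b_tot) / copies
  q_new <- q_new / rowSums(q_new)
  f_new <- ifelse(f_den > 0, f_num / f_den, 0.5)
  f_new <- pmin(pmax(f_new, eps), 1 - eps)
  list(q = q_new, f = f_new, loglik = ll)
}

#' Fit an admixture model by EM
#'
#' Unsupervised admixture model: each of the two allele copies of individual
#' `i` at locus `j` originates from ancestral component `k` with probability
#' `q_ik` and is an insertion with probability `f_kj`, giving the binomial
#' genotype log-likelihood
#' `sum_ij g_ij log(sum_k q_ik f_kj) + (2 - g_ij) log(1 - sum_k q_ik f_kj)`.
#' Plain EM with multiple random restarts; the best run by final
#' log-likelihood is returned. The log-likelihood trace is non-decreasing
#' within every run.
#'
#' @param x [genotype_matrix()]; individuals must each have at least one
#'   typed locus.
#' @param k number of ancestral components, `1 <= k <=` individuals.
#' @param seed base RNG seed; restart `r` uses `seed + r - 1`.
#' @param tol stop when the log-likelihood increase falls below this.
#' @param max_iter iteration cap per restart.
#' @param n_restarts number of random initializations.
#' @return list of class `admixture_fit`: `q` (individuals x k, rows sum to
#'   1), `f` (k x loci, clipped to `[1e-6, 1 - 1e-6]`), `loglik_trace`,
#'   `loglik`, `k`, `seed` (of the winning restart), `iterations`,
#'   `converged`.
#' @export
admixture_em <- function(x, k, seed = 1L, tol = 1e-6, max_iter = 500L,
                         n_restarts = 5L) {
  stopifnot(inherits(x, "genotype_matrix"), k >= 1L)
  g <- unclass(x)
  storage.mode(g) <- "double"
  if (k > nrow(g)) stop("k exceeds the number of individuals", call. = FALSE)
  if (any(rowSums(!is.na(g)) == 0)) {
    stop("individual with no typed loci", call. = FALSE)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- with_seed(seed + r - 1L, {
      q <- matrix(stats::rgamma(nrow(g) * k, 1), nrow(g), k)
      q <- q / rowSums(q)
      f <- matrix(stats::runif(k * ncol(g), 0.05, 0.95), k, ncol(g))
      trace <- numeric(0)
      converged <- FALSE
      iter <- 0L
      while (iter < max_iter) {
        iter <- iter + 1L
        step <- .admixture_em_step(g, q, f)
        trace <- c(trace, step$loglik)
        if (iter > 1L && abs(trace[iter] - trace[iter - 1L]) < tol) {
          converged <- TRUE
          break
        }
        q <- step$q
        f <- step$f
      }
      list(q = q, f = f, trace = trace, converged = converged, iter = iter,
           seed = seed + r - 1L)
    })
    if (is.null(best) || max(fit$trace) > max(best$trace)) best <- fit
  }
  dimnames(best$q) <- list(rownames(g), paste0("K", seq_len(k)))
  dimnames(best$f) <- list(paste0("K", seq_len(k)), colnames(g))
  structure(list(q = best$q, f = best$f, loglik_trace = best$trace,
                 loglik = best$trace[length(best$trace)], k = as.integer(k),
                 seed = best$seed, iterations = best$iter,
                 converged = best$converged),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat("<admixture_fit> K=", x$k, ", ", nrow(x$q), " individuals, ",
      ncol(x$f), " loci; loglik ", format(x$loglik, digits = 8),
      if (x$converged) " (converged)" else " (max_iter reached)", "\n",
      sep = "")
  invisible(x)
}

# all permutations of 1..k as a list (k small)
.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (sub in .permutations(k - 1L)) {
    for (pos in seq_len(k)) {
      out[[length(out) + 1L]] <- append(sub, k, after = pos - 1L)
    }
  }
  out
}

# similarity between two ancestry columns: correlation where defined,
# negative mean absolute difference for (near-)constant columns
.column_similarity <- function(a, b) {
  if (stats::sd(a) < 1e-12 || stats::sd(b) < 1e-12) {
    -mean(abs(a - b))
  } else {
    stats::cor(a, b)
  }
}

#' Resolve label switching between two admixture fits
#'
#' Ancestral components are identified only up to permutation. Finds the
#' permutation of `fit_b`'s components that maximizes the summed similarity
#' (column correlation) with `fit_a`'s ancestry matrix, by exhaustive search
#' over all `k!` permutations.
#'
#' @param fit_a,fit_b `admixture_fit` objects (or plain Q matrices) with the
#'   same `k` and individuals.
#' @return integer permutation `perm` such that `fit_b$q[, perm]` matches
#'   `fit_a$q` component-wise.
#' @export
align_components <- function(fit_a, fit_b) {
  qa <- if (inherits(fit_a, "admixture_fit")) fit_a$q else as.matrix(fit_a)
  qb <- if (inherits(fit_b, "admixture_fit")) fit_b$q else as.matrix(fit_b)
  if (ncol(qa) != ncol(qb)) stop("fits have different k", call. = FALSE)
  if (nrow(qa) != nrow(qb)) stop("fits cover different individuals", call. = FALSE)
  k <- ncol(qa)
  if (k > 8L) stop("exhaustive alignment supports k <= 8", call. = FALSE)
  sim <- outer(seq_len(k), seq_len(k), Vectorize(function(i, j) {
    .column_similarity(qa[, i], qb[, j])
  }))
  perms <- .permutations(k)
  scores <- vapply(perms, function(p) sum(sim[cbind(seq_len(k), p)]), numeric(1))
  perms[[which.max(scores)]]
}
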