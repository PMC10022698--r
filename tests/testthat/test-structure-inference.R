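test_that("neighbor joining reproduces the three-point closed form", {
  dm <- distance_matrix(matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3),
                        c("A", "B", "C"), "test")
  tree <- neighbor_joining(dm)
  # pendant branches (d_AB + d_AC - d_BC)/2 etc.
  lens <- setNames(tree$edge.length[match(seq_along(tree$tip.label),
                                          tree$edge[, 2])],
                   tree$tip.label)
  expect_equal(lens[["A"]], 0.5)
  expect_equal(lens[["B"]], 1.5)
  expect_equal(lens[["C"]], 2.5)
  expect_error(neighbor_joining(matrix(0, 2, 2)), ">= 3")
})

test_that("neighbor joining is exact on additive matrices", {
  set.seed(51)
  for (rep in 1:10) {
    n_tips <- sample(4:8, 1)
    true_tree <- ape::rtree(n_tips, rooted = FALSE)
    d <- ape::cophenetic.phylo(true_tree)
    rebuilt <- neighbor_joining(d)
    d2 <- ape::cophenetic.phylo(rebuilt)[rownames(d), colnames(d)]
    expect_equal(d2, d, tolerance = 1e-9)
  }
})

test_that("ultrametric four-leaf matrices recover the correct split", {
  # ((A,B),(C,D)): within-pair distance 2, across 6
  d <- matrix(6, 4, 4)
  d[1, 2] <- d[2, 1] <- 2
  d[3, 4] <- d[4, 3] <- 2
  diag(d) <- 0
  dimnames(d) <- list(c("A", "B", "C", "D"), c("A", "B", "C", "D"))
  tree <- neighbor_joining(d)
  splits <- ape::prop.part(ape::unroot(tree))
  pairs <- lapply(splits, function(s) sort(attr(splits, "labels")[s]))
  expect_true(any(vapply(pairs, identical, logical(1), y = c("A", "B"))) ||
                any(vapply(pairs, identical, logical(1), y = c("C", "D"))))
})

test_that("Newick output round-trips through an independent parser", {
  dm <- distance_matrix(matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3),
                        c("A", "B", "C"), "test")
  tree <- neighbor_joining(dm)
  path <- withr::local_tempfile(fileext = ".nwk")
  newick <- write_newick(tree, path)
  expect_match(newick, ";$")
  expect_true(grepl("A:0.5", newick, fixed = TRUE))
  back <- ape::read.tree(path)
  expect_setequal(back$tip.label, tree$tip.label)
  expect_equal(ape::cophenetic.phylo(back)[c("A", "B", "C"), c("A", "B", "C")],
               ape::cophenetic.phylo(tree)[c("A", "B", "C"), c("A", "B", "C")])

  # labels with metacharacters are quoted and tokenized as one label by the
  # independent parser (which retains the quote characters)
  tree$tip.label[1] <- "X Y"
  newick2 <- write_newick(tree, path)
  expect_true(grepl("'X Y'", newick2, fixed = TRUE))
  parsed <- gsub("^'|'$", "", ape::read.tree(path)$tip.label)
  expect_true("X Y" %in% parsed)
})

test_that("PCA: degenerate and rank-1 structures behave as expected", {
  same <- frequency_table(rbind(c(0.2, 0.6), c(0.2, 0.6)), c("P1", "P2"),
                          c("L1", "L2"), c(10L, 10L))
  expect_error(pca_frequencies(same), "constant")

  # three populations on a one-dimensional frequency gradient
  grad <- frequency_table(rbind(c(0.2, 0.3, 0.4), c(0.3, 0.4, 0.5),
                                c(0.4, 0.5, 0.6)),
                          paste0("P", 1:3), paste0("L", 1:3), rep(50L, 3))
  res <- pca_frequencies(grad)
  expect_gt(res$explained_fraction[1], 0.999)
})

test_that("PCA reconstruction from all components reproduces the centered matrix", {
  set.seed(61)
  m <- matrix(runif(6 * 20), 6, 20,
              dimnames = list(paste0("P", 1:6), paste0("L", 1:20)))
  ft <- frequency_table(m, rownames(m), colnames(m), rep(100L, 6))
  res <- pca_frequencies(ft)
  centered <- scale(m, center = TRUE, scale = FALSE)
  rebuilt <- res$scores %*% t(res$loadings)
  expect_lt(max(abs(rebuilt - centered)), 1e-10)
  expect_equal(sum(res$explained_fraction), 1, tolerance = 1e-12)
  expect_true(all(diff(res$explained_fraction) <= 1e-12))
})

test_that("admixture EM at K = 1 collapses to per-locus allele frequencies", {
  gm <- sample_hwe_population(c(0.2, 0.5, 0.8), 80, seed = 71)
  fit <- admixture_em(gm, 1, seed = 1, n_restarts = 1)
  expect_true(all(fit$q == 1))
  freqs <- vapply(1:3, function(j) insertion_frequency(tabulate_counts(gm, j)),
                  numeric(1))
  expect_equal(as.vector(fit$f), freqs, tolerance = 1e-4)
})

test_that("admixture EM recovers two-population structure and mixtures", {
  set.seed(81)
  # ancestry-informative panel: large frequency differentials between the
  # two source populations
  L <- 100L
  f_true <- rbind(runif(L, 0.05, 0.3), runif(L, 0.7, 0.95))
  q_true <- rbind(matrix(c(1, 0), 30, 2, byrow = TRUE),
                  matrix(c(0, 1), 30, 2, byrow = TRUE),
                  matrix(c(0.5, 0.5), 20, 2, byrow = TRUE))
  gm <- sample_admixed_population(q_true, f_true, seed = 82)
  fit <- admixture_em(gm, 2, seed = 83, n_restarts = 3, max_iter = 2000,
                      tol = 1e-8)

  expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  expect_equal(unname(rowSums(fit$q)), rep(1, nrow(fit$q)), tolerance = 1e-9)
  expect_true(all(fit$f >= 1e-6 & fit$f <= 1 - 1e-6))

  perm <- align_components(q_true, fit)
  q_hat <- fit$q[, perm]
  # unadmixed individuals assign almost fully to one component
  expect_gt(mean(apply(q_hat[1:60, ], 1, max)), 0.95)
  # 50/50 individuals recovered within 0.1 mean absolute error
  expect_lt(mean(abs(q_hat - q_true)), 0.1)
})

test_that("component alignment finds the best permutation", {
  set.seed(91)
  q <- matrix(rgamma(40 * 3, 1), 40, 3)
  q <- q / rowSums(q)
  expect_equal(align_components(q, q), 1:3)
  swap <- c(3L, 1L, 2L)
  # q[, swap][, perm] must equal q, so perm is the inverse permutation
  expect_equal(align_components(q, q[, swap]), order(swap))

  # random pair: matches exhaustive search over all k! permutations
  q2 <- matrix(rgamma(40 * 3, 1), 40, 3)
  q2 <- q2 / rowSums(q2)
  got <- align_components(q, q2)
  scores <- vapply(oracle_perms(3), function(p) {
    sum(vapply(1:3, function(i) cor(q[, i], q2[, p[i]]), numeric(1)))
  }, numeric(1))
  best <- oracle_perms(3)[[which.max(scores)]]
  expect_equal(got, best)

  expect_error(align_components(q, q[, 1:2]), "different k")
})
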