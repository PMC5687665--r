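test_that("SBM network generator honors extreme and default densities", {
  # p_within = 1, p_between = 0: disjoint cliques, one per module
  net <- generate_network(n_genes = 20, k_modules = 4, p_within = 1,
                          p_between = 0, seed = 1)
  A <- as.matrix(ndsnf:::raw_adjacency(net))
  mods <- net$modules[net$gene_ids]
  expect_true(all(A[outer(mods, mods, "!=")] == 0))
  for (m in unique(mods)) {
    block <- A[mods == m, mods == m]
    expect_true(all(block[upper.tri(block)] == 1))
  }

  # defaults: within-module density within 3 binomial SEs of p_within
  net2 <- generate_network(seed = 1)
  A2 <- as.matrix(ndsnf:::raw_adjacency(net2))
  mods2 <- net2$modules[net2$gene_ids]
  within_pairs <- sum(outer(mods2, mods2, "==") & upper.tri(A2))
  within_edges <- sum(A2[outer(mods2, mods2, "==") & upper.tri(A2)])
  phat <- within_edges / within_pairs
  se <- sqrt(0.3 * 0.7 / within_pairs)
  expect_lt(abs(phat - 0.3), 3 * se)
})

test_that("mutation generator is sparse, binary, Poisson-calibrated", {
  net <- generate_network(seed = 2)
  labels <- rep(1:3, length.out = 1000)
  muts <- generate_mutations(labels, net, lambda = 8, seed = 3)
  M <- as.matrix(muts[, -1])
  expect_true(all(M %in% c(0, 1)))
  mean_per_patient <- mean(rowSums(M))
  expect_gt(mean_per_patient, 7)
  expect_lt(mean_per_patient, 9)
  # sparsity: far fewer mutated genes than genes
  expect_lt(max(rowSums(M)), 0.1 * ncol(M))
})

test_that("near-zero lambda yields an (almost surely) empty matrix", {
  net <- generate_network(n_genes = 50, k_modules = 2, seed = 4)
  muts <- generate_mutations(rep(1:2, 10), net, lambda = 1e-9, seed = 5)
  expect_equal(sum(as.matrix(muts[, -1])), 0)
})

test_that("same-subtype patients share modules, not necessarily genes", {
  net <- generate_network(n_genes = 60, k_modules = 3, p_within = 1,
                          p_between = 0, seed = 6)
  muts <- generate_mutations(rep(1:3, each = 10), net, lambda = 4,
                             driver_fraction = 1, seed = 7)
  M <- as.matrix(muts[, -1])
  mods <- net$modules[colnames(M)]
  # with driver_fraction = 1 every mutation falls in the subtype module
  for (s in 1:3) {
    rows <- which(rep(1:3, each = 10) == s)
    hit_mods <- unique(mods[colSums(M[rows, , drop = FALSE]) > 0])
    expect_equal(hit_mods, s)
  }
})

test_that("continuous layers carry subtype signal scaled by delta", {
  labels <- rep(1:3, length.out = 60)
  x0 <- generate_continuous(labels, delta = 0, sigma = 1, seed = 8)
  x1 <- generate_continuous(labels, delta = 3, sigma = 0.1, seed = 8)
  # delta = 0: between-group mean differences are pure noise
  m0 <- as.matrix(x0[, -1])
  m1 <- as.matrix(x1[, -1])
  gap <- function(M) {
    g1 <- colMeans(M[labels == 1, ]); g2 <- colMeans(M[labels == 2, ])
    max(abs(g1 - g2))
  }
  expect_gt(gap(m1), gap(m0))
})

test_that("survival generator respects censoring controls", {
  labels <- rep(1:3, length.out = 90)
  s0 <- generate_survival(labels, censor_rate = 0, seed = 9)
  expect_true(all(s0$event == 1L))
  expect_true(all(s0$time >= 0 & is.finite(s0$time)))
  s1 <- generate_survival(labels, censor_rate = 5e-4, seed = 9)
  expect_gt(sum(s1$event == 0L), 0)
})

test_that("cohorts are bit-reproducible functions of the seed", {
  c1 <- generate_cohort(seed = 42, n_patients = 30, n_genes = 80)
  c2 <- generate_cohort(seed = 42, n_patients = 30, n_genes = 80)
  expect_identical(c1$layers, c2$layers)
  expect_identical(c1$mutations, c2$mutations)
  expect_identical(c1$network$edges, c2$network$edges)
  expect_identical(c1$survival, c2$survival)
  c3 <- generate_cohort(seed = 43, n_patients = 30, n_genes = 80)
  expect_false(identical(c1$mutations, c3$mutations))
})

test_that("benchmark regime: low gene overlap, yet recoverable subtypes", {
  co <- generate_cohort(seed = 7)
  M <- as.matrix(co$mutations[, -1])
  lab <- co$true_labels$subtype
  # average within-subtype Jaccard overlap of mutated gene sets
  jac <- c()
  withr::with_seed(1, {
    for (s in unique(lab)) {
      rows <- which(lab == s)
      pairs <- utils::combn(sample(rows, 10), 2)
      for (p in seq_len(ncol(pairs))) {
        a <- which(M[pairs[1, p], ] == 1)
        b <- which(M[pairs[2, p], ] == 1)
        jac <- c(jac, length(intersect(a, b)) / length(union(a, b)))
      }
    }
  })
  expect_lt(mean(jac), 0.1)
  # yet the full pipeline recovers the planted subtypes
  fit <- run_pipeline(co, snf_config(k_clusters = 3))
  expect_gte(fit$evaluation$ari, 0.9)
})
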