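test_that("similarity-to-distance transform is monotone with zero diagonal", {
  withr::with_seed(8, {
    Pc <- matrix(runif(49, 0.1, 0.9), 7)
    Pc <- (Pc + t(Pc)) / 2
    diag(Pc) <- 1
    dimnames(Pc) <- list(paste0("P", 1:7), paste0("P", 1:7))
    D <- similarity_to_distance(as_fused_network(Pc))
    expect_equal(unname(diag(D)), rep(0, 7))
    off <- upper.tri(Pc)
    # most similar pair maps to distance 0
    expect_equal(min(D[off]), 0)
    # strict monotonicity: higher similarity, smaller distance
    o <- order(Pc[off])
    expect_true(all(diff(D[off][o]) <= 0))
  })
  flat <- matrix(0.5, 3, 3, dimnames = list(paste0("P", 1:3), paste0("P", 1:3)))
  expect_error(similarity_to_distance(as_fused_network(flat)), "degenerate")
})

test_that("silhouette matches the ideal-separation and singleton conventions", {
  # two clusters, zero within / unit between distances: mean silhouette 1
  D <- matrix(1, 6, 6)
  D[1:3, 1:3] <- 0
  D[4:6, 4:6] <- 0
  dimnames(D) <- list(paste0("P", 1:6), paste0("P", 1:6))
  lab <- tibble::tibble(patient_id = paste0("P", 1:6),
                        cluster = rep(1:2, each = 3))
  s <- silhouette_score(lab, D)
  expect_equal(s$mean, 1)

  # singleton cluster contributes 0 by convention
  lab2 <- tibble::tibble(patient_id = paste0("P", 1:6),
                         cluster = c(1, 1, 1, 2, 2, 3))
  s2 <- silhouette_score(lab2, D)
  expect_equal(s2$scores$silhouette[6], 0)

  expect_error(
    silhouette_score(tibble::tibble(patient_id = paste0("P", 1:6),
                                    cluster = rep(1, 6)), D),
    "one cluster")
})

test_that("silhouette equals the exhaustive brute-force oracle", {
  withr::with_seed(23, {
    for (rep in 1:20) {
      n <- sample(6:15, 1)
      k <- sample(2:3, 1)
      X <- matrix(rnorm(n * 2), n)
      D <- as.matrix(dist(X))
      dimnames(D) <- list(sprintf("P%02d", 1:n), sprintf("P%02d", 1:n))
      cl <- sample(rep(seq_len(k), length.out = n))
      lab <- tibble::tibble(patient_id = rownames(D), cluster = cl)
      s <- silhouette_score(lab, D)
      expect_equal(s$scores$silhouette, silhouette_oracle(cl, D),
                   tolerance = 1e-12)
    }
  })
})

test_that("log-rank test matches the hand-computed hypergeometric formula", {
  surv <- tibble::tibble(patient_id = paste0("P", 1:6),
                         time = c(1, 2, 3, 4, 5, 6),
                         event = rep(1L, 6))
  lab <- tibble::tibble(patient_id = paste0("P", 1:6),
                        cluster = rep(1:2, each = 3))
  got <- logrank_test(lab, surv)
  want <- logrank_oracle(surv$time, surv$event, lab$cluster)
  expect_equal(got$statistic, want, tolerance = 1e-9)
  expect_equal(got$df, 1L)

  # three groups, censoring, ties
  withr::with_seed(40, {
    surv3 <- tibble::tibble(patient_id = sprintf("P%02d", 1:30),
                            time = sample(1:12, 30, replace = TRUE),
                            event = rbinom(30, 1, 0.7))
    lab3 <- tibble::tibble(patient_id = surv3$patient_id,
                           cluster = sample(rep(1:3, each = 10)))
  })
  got3 <- logrank_test(lab3, surv3)
  expect_equal(got3$statistic,
               logrank_oracle(surv3$time, surv3$event, lab3$cluster),
               tolerance = 1e-9)
  expect_equal(got3$df, 2L)
})

test_that("log-rank degenerate and invariance properties hold", {
  # duplicated identical groups: no separation at all
  base <- tibble::tibble(time = c(3, 5, 8, 11), event = c(1L, 1L, 0L, 1L))
  surv <- tibble::tibble(patient_id = paste0("P", 1:8),
                         time = rep(base$time, 2),
                         event = rep(base$event, 2))
  lab <- tibble::tibble(patient_id = paste0("P", 1:8),
                        cluster = rep(1:2, each = 4))
  got <- logrank_test(lab, surv)
  expect_equal(got$statistic, 0, tolerance = 1e-12)
  expect_equal(got$p_value, 1)

  # relabeling groups and shifting all times leaves the statistic unchanged
  lab_sw <- dplyr::mutate(lab, cluster = 3L - cluster)
  surv_sh <- dplyr::mutate(surv, time = time + 100)
  expect_equal(logrank_test(lab_sw, surv_sh)$statistic, got$statistic)

  # all-censored cohorts are rejected
  cens <- dplyr::mutate(surv, event = 0L)
  expect_error(logrank_test(lab, cens), "no events")
})

test_that("adjusted Rand index matches the contingency-table oracle", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(1, 1, 2, 2)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  # all-singletons vs all-together has zero adjusted agreement
  expect_equal(adjusted_rand_index(1:4, rep(1, 4)), 0)
  withr::with_seed(77, {
    for (rep in 1:10) {
      n <- sample(8:20, 1)
      a <- sample(1:3, n, replace = TRUE)
      b <- sample(1:4, n, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b), ari_oracle(a, b),
                   tolerance = 1e-12)
    }
  })
  expect_error(
    adjusted_rand_index(
      tibble::tibble(patient_id = c("a", "b"), cluster = c(1, 2)),
      tibble::tibble(patient_id = c("a", "c"), cluster = c(1, 2))),
    "different patient sets")
})

test_that("compare_methods runs all modes and the single-layer bypass", {
  co <- generate_cohort(seed = 15, n_patients = 40, n_genes = 120)
  cmp <- compare_methods(co, snf_config(k_clusters = 3))
  expect_equal(cmp$method, c("continuous", "raw_mutations",
                             "smoothed_mutations"))
  expect_true(all(cmp$mean_silhouette >= -1 & cmp$mean_silhouette <= 1))
  expect_true(all(cmp$logrank_p > 0 & cmp$logrank_p <= 1))

  # one continuous layer, no mutations: degenerates to single-view clustering
  co1 <- as_snf_cohort(co$layers[1], survival = co$survival,
                       true_labels = co$true_labels)
  cmp1 <- compare_methods(co1, snf_config(k_clusters = 3),
                          methods = "continuous")
  expect_equal(nrow(cmp1), 1L)
  expect_false(is.na(cmp1$ari))

  expect_error(compare_methods(co1, methods = "smoothed_mutations"),
               "mutation layer required")
})
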