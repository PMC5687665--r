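test_that("degree normalization matches hand-computed cases", {
  # single edge: both nodes degree 1
  net <- gene_network(tibble::tibble(from = "g1", to = "g2"))
  A <- as.matrix(normalize_adjacency(net))
  expect_equal(unname(A), matrix(c(0, 1, 1, 0), 2))

  # triangle: every off-diagonal 0.5
  tri <- gene_network(tibble::tibble(from = c("g1", "g2", "g1"),
                                     to = c("g2", "g3", "g3")))
  At <- as.matrix(normalize_adjacency(tri))
  expect_equal(unname(At), matrix(c(0, .5, .5, .5, 0, .5, .5, .5, 0), 3))

  # path a-b-c: middle row splits, end rows are a single 1
  pth <- gene_network(tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  Ap <- as.matrix(normalize_adjacency(pth))
  expect_equal(Ap["b", ], c(a = 0.5, b = 0, c = 0.5))
  expect_equal(Ap["a", ], c(a = 0, b = 1, c = 0))
  expect_equal(Ap["c", ], c(a = 0, b = 1, c = 0))

  # isolated genes keep an all-zero row
  iso <- normalize_adjacency(net, genes = c("g1", "g2", "lonely"))
  expect_equal(as.numeric(iso["lonely", ]), c(0, 0, 0))
})

test_that("propagation limits behave: restart-only, fixed point, empty net", {
  A <- row_normalize(random_adjacency(6))
  F0 <- matrix(rbinom(12, 1, 0.4), 2, 6,
               dimnames = list(c("P1", "P2"), rownames(A)))
  # alpha = 0: restart only, F stays at F0
  r0 <- propagate(F0, A, alpha = 0)
  expect_equal(r0$smoothed, F0)
  expect_equal(r0$n_iterations, 1L)

  # uniform rows + doubly stochastic A: F0 is a fixed point
  n <- 4
  Ad <- matrix(1 / n, n, n)  # doubly stochastic
  Fu <- matrix(1 / n, 2, n)
  ru <- propagate(Fu, Ad, alpha = 0.6)
  expect_equal(ru$smoothed, Fu, tolerance = 1e-9)

  # no edges: only the scaled restart term survives
  Az <- matrix(0, 3, 3)
  Fz <- matrix(c(1, 0, 1, 1, 0, 0), 2, 3)
  rz <- propagate(Fz, Az, alpha = 0.7)
  expect_equal(rz$smoothed, closed_form_solve(Fz, Az, 0.7), tolerance = 1e-9)
  expect_equal(rz$smoothed, 0.3 * Fz, tolerance = 1e-9)
})

test_that("iterative propagation agrees with the closed-form linear solve", {
  # 3-gene path, one patient mutated at one end
  A <- matrix(c(0, 1, 0, .5, 0, .5, 0, 1, 0), 3, byrow = TRUE)
  F0 <- matrix(c(1, 0, 0), 1, 3)
  r <- propagate(F0, A, alpha = 0.5, tol = 1e-12)
  expect_lt(max(abs(r$smoothed - closed_form_solve(F0, A, 0.5))), 1e-9)

  # random instances
  withr::with_seed(42, {
    for (rep in 1:10) {
      ng <- sample(4:20, 1)
      np <- sample(1:6, 1)
      A <- row_normalize(random_adjacency(ng))
      F0 <- matrix(rbinom(np * ng, 1, 0.3), np, ng)
      alpha <- runif(1, 0.4, 0.85)
      r <- propagate(F0, A, alpha = alpha, tol = 1e-8)
      expect_lt(max(abs(r$smoothed - closed_form_solve(F0, A, alpha))), 1e-7)
      expect_true(all(r$smoothed >= 0))
      expect_lt(r$final_delta, 1e-8)
    }
  })
})

test_that("diffusion respects locality and keeps mutated genes positive", {
  # two disconnected components: a-b and c-d
  net <- gene_network(tibble::tibble(from = c("a", "c"), to = c("b", "d")))
  A <- normalize_adjacency(net)
  F0 <- matrix(c(1, 0, 0, 0), 1, 4, dimnames = list("P1", c("a", "b", "c", "d")))
  r <- propagate(F0, A, alpha = 0.7)
  expect_equal(as.numeric(r$smoothed[, c("c", "d")]), c(0, 0))   # locality
  expect_gt(r$smoothed[, "a"], 0)                                 # retained
  expect_gt(r$smoothed[, "b"], 0)                                 # neighbor gain

  # monotone influence of alpha on an unmutated neighbor
  got <- vapply(c(0.5, 0.65, 0.8), function(al)
    propagate(F0, A, alpha = al, tol = 1e-10)$smoothed[, "b"], numeric(1))
  expect_true(all(diff(got) > 0))
})

test_that("propagate validates alignment and alpha", {
  A <- row_normalize(random_adjacency(4))
  F0 <- matrix(0, 1, 4, dimnames = list("P1", rev(rownames(A))))
  expect_error(propagate(F0, A, 0.5), "misaligned")
  expect_error(propagate(matrix(0, 1, 3), A, 0.5), "misaligned")
  expect_error(propagate(matrix(0, 1, 4), A, 1), "alpha")
})

test_that("network_smooth handles genes missing from the network", {
  net <- gene_network(tibble::tibble(from = "g1", to = "g2"))
  muts <- dplyr::bind_cols(
    tibble::tibble(patient_id = c("P1", "P2")),
    tibble::as_tibble(matrix(c(1, 0, 0, 1), 2, 2,
                             dimnames = list(NULL, c("g1", "orphan"))))
  )
  expect_message(sm <- network_smooth(muts, net, alpha = 0.6), "absent")
  info <- attr(sm, "diffusion")
  expect_equal(info$n_mutation_only_genes, 1L)
  expect_equal(info$n_network_only_genes, 1L)
  # orphan gene keeps only its restart signal: (1 - alpha) * F0
  expect_equal(sm$orphan, c(0, 0.4), tolerance = 1e-9)
  # unmutated network gene g2 receives propagated signal for P1
  expect_gt(sm$g2[1], 0)
})

test_that("smooth_rescale max-normalizes rows and preserves zeros", {
  m <- matrix(c(0.2, 0.4, 0, 0), 2, 2, byrow = TRUE,
              dimnames = list(c("P1", "P2"), c("g1", "g2")))
  out <- smooth_rescale(m)
  expect_equal(out["P1", ], c(g1 = 0.5, g2 = 1))
  expect_equal(out["P2", ], c(g1 = 0, g2 = 0))
})
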