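# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# exhaustive silhouette: loops over every pair of patients
silhouette_oracle <- function(cl, D) {
  n <- length(cl)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- Inf
    for (g in setdiff(unique(cl), cl[i]))
      b <- min(b, mean(D[i, which(cl == g)]))
    s[i] <- (b - a) / max(a, b)
  }
  s
}

# k-sample log-rank statistic from first principles (hypergeometric model)
logrank_oracle <- function(time, event, group) {
  groups <- sort(unique(group))
  k <- length(groups)
  times <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in times) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    d_t <- sum(event == 1 & time == t)
    if (n_t < 1 || d_t == 0) next
    for (j in seq_len(k)) {
      nj <- sum(at_risk & group == groups[j])
      dj <- sum(event == 1 & time == t & group == groups[j])
      O[j] <- O[j] + dj
      E[j] <- E[j] + d_t * nj / n_t
    }
    if (n_t > 1) {
      for (j in seq_len(k)) for (l in seq_len(k)) {
        nj <- sum(at_risk & group == groups[j])
        nl <- sum(at_risk & group == groups[l])
        V[j, l] <- V[j, l] +
          d_t * (n_t - d_t) / (n_t - 1) *
          (nj / n_t) * ((j == l) - nl / n_t)
      }
    }
  }
  z <- (O - E)[-1]
  as.numeric(t(z) %*% solve(V[-1, -1, drop = FALSE], z))
}

# adjusted Rand index straight from the pair-counting contingency table
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(0)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}

# one fusion round computed entrywise with explicit loops, mirroring the
# update P(v) <- S(v) (mean of other views' P) S(v)^T followed by
# symmetrization and half-mass row renormalization
fusion_round_oracle <- function(Ps, Ss) {
  m <- length(Ps)
  n <- nrow(Ps[[1]])
  out <- vector("list", m)
  for (v in seq_len(m)) {
    Pbar <- matrix(0, n, n)
    for (w in seq_len(m)) if (w != v) Pbar <- Pbar + Ps[[w]]
    Pbar <- Pbar / (m - 1)
    Pnew <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in seq_len(n)) {
      acc <- 0
      for (a in seq_len(n)) for (b in seq_len(n))
        acc <- acc + Ss[[v]][i, a] * Pbar[a, b] * Ss[[v]][j, b]
      Pnew[i, j] <- acc
    }
    Pnew <- (Pnew + t(Pnew)) / 2
    for (i in seq_len(n)) {
      off <- sum(Pnew[i, ]) - Pnew[i, i]
      Pnew[i, -i] <- Pnew[i, -i] / (2 * off)
      Pnew[i, i] <- 0.5
    }
    out[[v]] <- Pnew
  }
  out
}

# random small cohort for contract checks
random_feature_tbl <- function(n, p, ids = sprintf("P%02d", seq_len(n))) {
  m <- matrix(rnorm(n * p), n, p,
              dimnames = list(ids, sprintf("f%02d", seq_len(p))))
  dplyr::bind_cols(tibble::tibble(patient_id = ids), tibble::as_tibble(m))
}

# random connected-ish adjacency for diffusion checks (symmetric 0/1)
random_adjacency <- function(n_genes, p_edge = 0.25) {
  A <- matrix(rbinom(n_genes^2, 1, p_edge), n_genes)
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  diag(A) <- 0
  dimnames(A) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("g%02d", seq_len(n_genes)))
  A
}

row_normalize <- function(A) {
  d <- rowSums(A)
  d[d == 0] <- 1
  A / d
}

# hand-built kernel pair on explicit W (bypasses distances)
kernel_from_W <- function(W, K) {
  ids <- rownames(W)
  P <- global_kernel(W)
  loc <- local_kernel(W, K)
  structure(list(W = W, P = P, S = loc$S, neighbor_sets = loc$neighbor_sets,
                 patient_ids = ids, mu = NA_real_, K = K, metric = "euclidean"),
            class = "snf_kernel")
}
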