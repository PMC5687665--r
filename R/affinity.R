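#' Pairwise patient distances
#'
#' Computes the full symmetric patient-by-patient distance matrix for one
#' data layer. Euclidean distance suits continuous omics; the histogram
#' chi-squared distance
#' \deqn{d(x, y) = \sqrt{\sum_f (x_f - y_f)^2 / (x_f + y_f)}}
#' (summing over features with \eqn{x_f + y_f > 0}) is the discrete-data
#' alternative and requires nonnegative values.
#'
#' @param data Feature tibble (first column `patient_id`) or numeric matrix
#'   with patient rownames.
#' @param metric `"euclidean"` or `"chi_squared"`.
#' @param standardize Center/scale each feature to zero mean and unit
#'   variance before computing distances (constant features are left at
#'   zero). Recommended for continuous layers so the kernel bandwidth scale
#'   is comparable across layers; not for smoothed mutation profiles.
#' @return Symmetric distance matrix with zero diagonal, patient dimnames
#'   and attribute `metric`.
#' @export
pairwise_distance <- function(data, metric = c("euclidean", "chi_squared"),
                              standardize = FALSE) {
  metric <- match.arg(metric)
  X <- if (is.data.frame(data)) ft_matrix(data) else data
  if (nrow(X) < 2L) abort("need at least 2 patients")
  if (standardize) {
    X <- scale(X)
    X[, attr(X, "scaled:scale") == 0] <- 0
    X[is.na(X)] <- 0
  }
  if (metric == "euclidean") {
    D <- as.matrix(dist(X))
  } else {
    if (any(X < 0)) abort("chi_squared distance requires nonnegative data")
    n <- nrow(X)
    D <- matrix(0, n, n, dimnames = list(rownames(X), rownames(X)))
    for (i in seq_len(n - 1L)) {
      xi <- X[i, ]
      rest <- X[(i + 1L):n, , drop = FALSE]
      s <- sweep(rest, 2, xi, `+`)
      d2 <- sweep(rest, 2, xi, `-`)^2
      ok <- s > 0
      d2[!ok] <- 0
      s[!ok] <- 1
      v <- sqrt(rowSums(d2 / s))
      D[i, (i + 1L):n] <- v
      D[(i + 1L):n, i] <- v
    }
  }
  diag(D) <- 0
  attr(D, "metric") <- metric
  D
}

#' Scaled exponential similarity kernel
#'
#' Converts a distance matrix into a patient affinity matrix
#' \deqn{W(i,j) = \exp\left(-\frac{d(i,j)^2}{\mu\,\varepsilon_{i,j}}\right)}
#' with the adaptive per-pair bandwidth
#' \deqn{\varepsilon_{i,j} = \frac{\overline{d}(i, N_i) + \overline{d}(j, N_j) + d(i,j)}{3}}
#' where \eqn{\overline{d}(i, N_i)} is the mean distance from patient i to
#' its K nearest other patients. The self-distance is excluded from the
#' neighbor mean so the bandwidth is not systematically deflated.
#'
#' @param D Symmetric distance matrix (e.g. from [pairwise_distance()]).
#' @param mu Bandwidth scale; recommended range \[0.3, 0.8\].
#' @param K Number of nearest neighbors entering the bandwidth.
#' @return Symmetric affinity matrix with unit diagonal, entries in (0, 1],
#'   attributes `mu` and `K`.
#' @export
scaled_exponential_kernel <- function(D, mu = 0.5, K = 20) {
  n <- nrow(D)
  if (mu <= 0) abort("mu must be positive")
  K <- as.integer(K)
  if (K < 1L || K >= n) abort("K must satisfy 1 <= K < n")
  if (all(D == 0)) {
    warn("all pairwise distances are zero (duplicate cohort); W = all ones")
    W <- matrix(1, n, n, dimnames = dimnames(D))
    attr(W, "mu") <- mu; attr(W, "K") <- K
    return(W)
  }
  # mean distance to the K nearest *other* patients
  knn_mean <- vapply(seq_len(n), function(i) {
    mean(sort(D[i, -i], partial = K)[seq_len(K)])
  }, numeric(1))
  eps <- (outer(knn_mean, knn_mean, `+`) + D) / 3
  W <- exp(-D^2 / (mu * eps))
  W[D == 0] <- 1          # includes the diagonal and exact duplicates
  W <- (W + base::t(W)) / 2
  dimnames(W) <- dimnames(D)
  attr(W, "mu") <- mu
  attr(W, "K") <- K
  W
}

#' Global (full) row-stochastic kernel P
#'
#' Normalizes the affinity matrix so each row's off-diagonal entries carry
#' half the mass and the diagonal the other half:
#' `P(i,j) = W(i,j) / (2 * sum_{k != i} W(i,k))` for `j != i`, and
#' `P(i,i) = 1/2`. Rows sum to one exactly.
#'
#' @param W Affinity matrix from [scaled_exponential_kernel()].
#' @return Row-stochastic matrix `P` with diagonal 1/2.
#' @export
global_kernel <- function(W) {
  Wo <- W
  diag(Wo) <- 0                  # avoids cancellation when offdiag << diag
  off <- rowSums(Wo)
  if (any(off <= 0)) abort("patient with zero off-diagonal similarity")
  P <- W / (2 * off)
  diag(P) <- 0.5
  dimnames(P) <- dimnames(W)
  P
}

#' Local KNN-restricted kernel S
#'
#' For each patient i, keeps only the neighborhood `N_i` = \{i\} plus the K
#' patients most similar to i (ties at the cutoff broken by patient order)
#' and row-normalizes the retained similarities; all other entries are zero.
#'
#' @param W Affinity matrix.
#' @param K Neighborhood size (1 <= K < n).
#' @return List with `S` (row-stochastic sparse-in-structure matrix) and
#'   `neighbor_sets` (list of integer index vectors including self).
#' @export
local_kernel <- function(W, K) {
  n <- nrow(W)
  K <- as.integer(K)
  if (K < 1L || K >= n) abort("K must satisfy 1 <= K < n")
  S <- matrix(0, n, n, dimnames = dimnames(W))
  nbrs <- vector("list", n)
  for (i in seq_len(n)) {
    ord <- order(-W[i, ], seq_len(n))   # stable: ties by patient order
    ord <- ord[ord != i]
    Ni <- c(i, ord[seq_len(K)])
    S[i, Ni] <- W[i, Ni] / sum(W[i, Ni])
    nbrs[[i]] <- sort(Ni)
  }
  list(S = S, neighbor_sets = nbrs)
}

#' Build the full kernel pair for one data layer
#'
#' Convenience wrapper running [pairwise_distance()],
#' [scaled_exponential_kernel()], [global_kernel()] and [local_kernel()] for
#' one layer, producing the inputs that similarity network fusion consumes.
#'
#' @inheritParams pairwise_distance
#' @param mu Bandwidth scale.
#' @param K Neighborhood size; `NULL` picks `max(10, round(n/10))` capped at
#'   `n - 1`.
#' @return An object of class `snf_kernel`: list with `W`, `P`, `S`,
#'   `neighbor_sets`, `patient_ids`, `mu`, `K`, `metric`.
#' @export
#' @examples
#' X <- tibble::tibble(patient_id = paste0("P", 1:6),
#'                     f1 = rnorm(6), f2 = rnorm(6))
#' affinity_kernel(X, K = 2)
affinity_kernel <- function(data, metric = c("euclidean", "chi_squared"),
                            mu = 0.5, K = NULL, standardize = FALSE) {
  metric <- match.arg(metric)
  D <- pairwise_distance(data, metric = metric, standardize = standardize)
  n <- nrow(D)
  K <- resolve_K(K, n)
  W <- scaled_exponential_kernel(D, mu = mu, K = K)
  P <- global_kernel(W)
  loc <- local_kernel(W, K)
  structure(
    list(W = W, P = P, S = loc$S, neighbor_sets = loc$neighbor_sets,
         patient_ids = rownames(D), mu = mu, K = K, metric = metric),
    class = "snf_kernel"
  )
}

#' @export
print.snf_kernel <- function(x, ...) {
  cat("<snf_kernel> ", length(x$patient_ids), " patients; metric = ",
      x$metric, ", mu = ", x$mu, ", K = ", x$K, "\n", sep = "")
  invisible(x)
}
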