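# ascending eigenvalues/vectors of the symmetric normalized Laplacian
# L = I - D^{-1/2} Pc D^{-1/2}
laplacian_eigen <- function(fused) {
  Pc <- fused$Pc
  if (any(!is.finite(Pc))) abort("non-finite entries in fused network")
  deg <- rowSums(Pc)
  bad <- which(deg <= 0)
  if (length(bad) > 0)
    abort(paste0("zero-degree patient in fused network: ",
                 fused$patient_ids[bad[1]]))
  dhalf <- 1 / sqrt(deg)
  L <- diag(nrow(Pc)) - (dhalf * Pc) %*% diag(dhalf)
  L <- (L + base::t(L)) / 2
  e <- eigen(L, symmetric = TRUE)
  list(values = rev(e$values), vectors = e$vectors[, rev(seq_len(ncol(e$vectors))), drop = FALSE])
}

#' Spectral clustering of a fused patient network
#'
#' Normalized-cuts spectral clustering: forms the symmetric normalized
#' Laplacian of the fused similarity matrix, takes the eigenvectors of its
#' k smallest eigenvalues, unit-normalizes the embedding rows, and runs
#' k-means with 50 seeded restarts (best within-cluster sum of squares
#' kept), so results are deterministic given the seed.
#'
#' @param fused A `fused_network` (from [snf_fuse()] or
#'   [as_fused_network()]).
#' @param k Number of clusters, or `"auto"` for eigengap selection via
#'   [estimate_num_clusters()].
#' @param seed Integer seed for the k-means restarts.
#' @param k_min,k_max Search range used when `k = "auto"`.
#' @return An object of class `snf_clustering`: list with `labels` (tibble
#'   `patient_id`, `cluster` with contiguous integer labels 1..k), `k`,
#'   `eigenvalues` (leading Laplacian spectrum, for diagnostics) and `seed`.
#' @export
spectral_cluster <- function(fused, k = "auto", seed = 1L,
                             k_min = 2, k_max = 10) {
  n <- length(fused$patient_ids)
  eig <- laplacian_eigen(fused)
  if (identical(k, "auto")) {
    k <- eigengap_k(eig$values, k_min = k_min, k_max = min(k_max, n - 1L))
  }
  k <- as.integer(k)
  if (k < 1L || k > n) abort("k must satisfy 1 <= k <= n")
  if (k == 1L) {
    cl <- rep(1L, n)
  } else {
    U <- eig$vectors[, seq_len(k), drop = FALSE]
    nrm <- sqrt(rowSums(U^2))
    nrm[nrm == 0] <- 1
    U <- U / nrm
    km <- withr::with_seed(seed, kmeans(U, centers = k, nstart = 50,
                                        iter.max = 100))
    cl <- relabel_contiguous(km$cluster)
  }
  structure(
    list(labels = tibble(patient_id = fused$patient_ids,
                         cluster = as.integer(cl)),
         k = k,
         eigenvalues = eig$values[seq_len(min(n, max(k + 5L, 12L)))],
         seed = as.integer(seed)),
    class = "snf_clustering"
  )
}

# relabel clusters 1..k in order of first appearance (determinism aid)
relabel_contiguous <- function(cl) {
  match(cl, unique(cl))
}

#' Choose the number of clusters by the eigengap heuristic
#'
#' Picks k in `[k_min, k_max]` maximizing the gap between consecutive
#' ascending eigenvalues of the symmetric normalized Laplacian,
#' \eqn{\lambda_{k+1} - \lambda_k}; ties are broken toward the smallest k
#' (parsimony).
#'
#' @param fused A `fused_network`, or a numeric vector of ascending
#'   Laplacian eigenvalues.
#' @param k_min,k_max Search range (requires `k_max < n`).
#' @return Integer k.
#' @export
estimate_num_clusters <- function(fused, k_min = 2, k_max = 10) {
  values <- if (is.numeric(fused)) fused else laplacian_eigen(fused)$values
  eigengap_k(values, k_min, min(k_max, length(values) - 1L))
}

eigengap_k <- function(values, k_min, k_max) {
  k_min <- as.integer(k_min); k_max <- as.integer(k_max)
  if (k_max < k_min) abort("k_max must be >= k_min")
  ks <- k_min:k_max
  gaps <- values[ks + 1L] - values[ks]
  ks[which.max(gaps)]   # which.max takes the first maximum: smallest k on ties
}

#' @export
print.snf_clustering <- function(x, ...) {
  cat("<snf_clustering> k = ", x$k, "; cluster sizes: ",
      paste(table(x$labels$cluster), collapse = ", "), "\n", sep = "")
  invisible(x)
}
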