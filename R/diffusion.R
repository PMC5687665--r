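#' Degree-normalized adjacency of a gene network
#'
#' Builds the (sparse) adjacency matrix of the network over a given gene
#' order and degree-normalizes it. The default random-walk normalization
#' divides each non-isolated gene's row by its weighted degree, giving a
#' row-stochastic matrix on non-isolated genes; isolated genes keep an
#' all-zero row. The symmetric variant D^(-1/2) A D^(-1/2) is available
#' as an alternative.
#'
#' @param network A [gene_network()] or a symmetric nonnegative adjacency
#'   matrix with dimnames.
#' @param genes Gene order for the result; defaults to the network's genes.
#'   Genes absent from the network get zero rows/columns (they neither send
#'   nor receive diffusion signal).
#' @param method `"row"` (random walk, default) or `"symmetric"`.
#' @return A sparse `Matrix` of dimension `length(genes)` squared.
#' @export
normalize_adjacency <- function(network, genes = NULL,
                                method = c("row", "symmetric")) {
  method <- match.arg(method)
  A <- raw_adjacency(network, genes)
  if (any(A@x < 0)) abort("negative weights in adjacency")
  dn <- dimnames(A)
  deg <- Matrix::rowSums(A)
  nz <- deg > 0
  if (method == "row") {
    inv <- ifelse(nz, 1 / deg, 0)
    A <- Diagonal(x = inv) %*% A
  } else {
    inv <- ifelse(nz, 1 / sqrt(deg), 0)
    A <- Diagonal(x = inv) %*% A %*% Diagonal(x = inv)
  }
  dimnames(A) <- dn
  A
}

# symmetric sparse adjacency over an explicit gene order
raw_adjacency <- function(network, genes = NULL) {
  if (inherits(network, "gene_network")) {
    genes <- genes %||% network$gene_ids
    e <- network$edges
    i <- match(e$from, genes)
    j <- match(e$to, genes)
    keep <- !is.na(i) & !is.na(j)
    A <- sparseMatrix(i = c(i[keep], j[keep]), j = c(j[keep], i[keep]),
                      x = rep(e$weight[keep], 2),
                      dims = c(length(genes), length(genes)),
                      dimnames = list(genes, genes))
  } else {
    A <- methods::as(methods::as(Matrix::Matrix(network, sparse = TRUE),
                                 "generalMatrix"), "CsparseMatrix")
    if (is.null(rownames(A))) abort("adjacency matrix needs dimnames")
    if (!Matrix::isSymmetric(A)) abort("adjacency must be symmetric")
    if (!is.null(genes)) {
      full <- sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(length(genes), length(genes)),
                           dimnames = list(genes, genes))
      common <- intersect(genes, rownames(A))
      full[common, common] <- A[common, common]
      A <- full
    }
  }
  A
}

#' Iterative network diffusion of mutation profiles
#'
#' Smooths a binary patient-by-gene matrix `F0` over a gene network by the
#' random-walk-with-restart iteration
#' \deqn{F_{t+1} = \alpha F_t A + (1 - \alpha) F_0}
#' where `A` is the degree-normalized adjacency. Iteration stops when the
#' maximum absolute elementwise change drops below `tol`. For row-stochastic
#' `A` and `alpha < 1` the map is a contraction, so convergence is
#' guaranteed; an iteration cap of 10,000 guards pathological inputs.
#'
#' @param F0 Numeric patients-by-genes matrix (columns aligned to `A`).
#' @param A Degree-normalized adjacency from [normalize_adjacency()].
#' @param alpha Restart weight in (0, 1).
#' @param tol Convergence tolerance (max absolute change). Default 1e-6.
#' @param max_iter Iteration cap.
#' @return A `diffusion_result`: list with `smoothed` (matrix), `n_iterations`
#'   and `final_delta`.
#' @export
propagate <- function(F0, A, alpha, tol = 1e-6, max_iter = 10000L) {
  # alpha = 0 is the restart-only limit (returns F0 after one iteration)
  if (alpha < 0 || alpha >= 1) abort("alpha must lie in [0, 1)")
  if (ncol(F0) != nrow(A)) abort("F0 columns misaligned with adjacency")
  if (!is.null(colnames(F0)) && !is.null(rownames(A)) &&
      !identical(colnames(F0), rownames(A)))
    abort("F0 gene order misaligned with adjacency gene order")
  Fc <- as.matrix(F0)
  restart <- (1 - alpha) * Fc
  delta <- Inf
  it <- 0L
  while (delta >= tol) {
    if (it >= max_iter)
      abort(paste0("diffusion did not converge within ", max_iter,
                   " iterations (delta = ", signif(delta, 3), ")"))
    Fn <- as.matrix(alpha * (Fc %*% A)) + restart
    delta <- max(abs(Fn - Fc))
    Fc <- Fn
    it <- it + 1L
  }
  structure(list(smoothed = Fc, n_iterations = it, final_delta = delta),
            class = "diffusion_result")
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat("<diffusion_result> ", nrow(x$smoothed), " patients x ",
      ncol(x$smoothed), " genes; converged in ", x$n_iterations,
      " iterations (final delta ", signif(x$final_delta, 3), ")\n", sep = "")
  invisible(x)
}

#' Closed-form stationary solution of the diffusion iteration
#'
#' The fixed point of the diffusion map is
#' \eqn{F_\infty = (1-\alpha) F_0 (I - \alpha A)^{-1}}, computed here by a
#' direct linear solve. Used as an exact oracle against [propagate()].
#'
#' @inheritParams propagate
#' @return Numeric matrix of the same shape as `F0`.
#' @export
closed_form_solve <- function(F0, A, alpha) {
  if (alpha < 0 || alpha >= 1) abort("alpha must lie in [0, 1)")
  n <- nrow(A)
  M <- diag(n) - alpha * as.matrix(A)
  # F (I - aA)^{-1}  <=>  solve t(I - aA) X = t(F), X = t(result)
  base::t(solve(base::t(M), base::t((1 - alpha) * as.matrix(F0))))
}

#' Smooth binary mutation profiles over a gene network
#'
#' Tidy front end to [propagate()]: takes a binary feature tibble of
#' mutation calls and a gene network, aligns the gene spaces (the union of
#' mutation genes and network genes — mutation genes missing from the
#' network keep zero adjacency and only retain their restart signal, while
#' network genes not in the mutation table can still receive propagated
#' signal), runs the diffusion to convergence and returns the smoothed
#' quantitative profiles.
#'
#' @param mutations Binary feature tibble (first column `patient_id`).
#' @param network A [gene_network()].
#' @param alpha Restart weight in (0, 1); recommended range \[0.5, 0.8\].
#' @param tol Convergence tolerance. Default 1e-6.
#' @param rescale If `TRUE`, rescale each patient's smoothed row to \[0, 1\]
#'   by its maximum (all-zero rows are left as zeros). Default `FALSE`.
#' @param normalization Adjacency normalization, see [normalize_adjacency()].
#' @return Feature tibble of smoothed profiles with attribute `diffusion`
#'   (list: `n_iterations`, `final_delta`, `n_mutation_only_genes`,
#'   `n_network_only_genes`).
#' @export
network_smooth <- function(mutations, network, alpha = 0.7, tol = 1e-6,
                           rescale = FALSE,
                           normalization = c("row", "symmetric")) {
  normalization <- match.arg(normalization)
  F0 <- ft_matrix(mutations)
  mut_genes <- colnames(F0)
  genes <- union(mut_genes, network$gene_ids)
  n_mut_only <- length(setdiff(mut_genes, network$gene_ids))
  n_net_only <- length(setdiff(network$gene_ids, mut_genes))
  if (n_mut_only > 0)
    inform(paste0(n_mut_only, " mutated gene(s) absent from the network",
                  " (kept with zero adjacency)"))
  A <- normalize_adjacency(network, genes = genes, method = normalization)
  F0full <- matrix(0, nrow(F0), length(genes),
                   dimnames = list(rownames(F0), genes))
  F0full[, mut_genes] <- F0
  res <- propagate(F0full, A, alpha = alpha, tol = tol)
  sm <- res$smoothed
  if (rescale) sm <- smooth_rescale(sm)
  out <- ft_tibble(sm, dtype = "continuous")
  attr(out, "diffusion") <- list(
    n_iterations = res$n_iterations, final_delta = res$final_delta,
    n_mutation_only_genes = n_mut_only, n_network_only_genes = n_net_only
  )
  out
}

#' Per-patient max rescaling of smoothed profiles
#'
#' Divides each patient's row by its maximum so profiles lie in \[0, 1\];
#' all-zero rows are returned unchanged.
#'
#' @param x Numeric matrix or feature tibble.
#' @return Same type as the input.
#' @export
smooth_rescale <- function(x) {
  if (is.data.frame(x)) {
    m <- ft_matrix(x)
    return(ft_tibble(smooth_rescale(m), dtype = attr(x, "dtype") %||% "continuous"))
  }
  mx <- apply(x, 1, max)
  mx[mx == 0] <- 1
  x / mx
}
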