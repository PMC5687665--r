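#' Run configuration
#'
#' Bundles every tunable of the pipeline with validation against the
#' recommended operating ranges: the kernel bandwidth scale `mu` should lie
#' in \[0.3, 0.8\] and the diffusion restart weight `alpha` in \[0.5, 0.8\]
#' (values outside trigger a warning; `alpha` outside (0, 1) is an error).
#'
#' @param mu Bandwidth scale of the scaled exponential kernel.
#' @param K Neighborhood size for the local kernel and the adaptive
#'   bandwidth; `NULL` picks `max(10, round(n/10))` (capped at `n - 1`) at
#'   run time.
#' @param t_fuse Number of fusion rounds.
#' @param alpha Diffusion restart weight in (0, 1); larger values propagate
#'   the mutation signal further from its source genes.
#' @param diff_tol Diffusion convergence tolerance on the max absolute
#'   elementwise change between iterations.
#' @param k_clusters Number of subtypes, or `"auto"` for eigengap selection.
#' @param k_min,k_max Search range for `"auto"` cluster selection.
#' @param seed Integer seed controlling the k-means restarts (and any other
#'   randomness downstream).
#' @param distance Named per-layer distance override (`"euclidean"` or
#'   `"chi_squared"`); unnamed layers default to Euclidean for continuous
#'   data.
#' @param rescale_smoothed Rescale each patient's smoothed mutation profile
#'   to \[0, 1\] by its maximum before computing distances (default on).
#'   Without it, Euclidean distances between smoothed profiles are dominated
#'   by per-patient mutation burden rather than by where in the network the
#'   signal sits, and low-burden patients collapse into a spurious
#'   near-zero cluster.
#' @param normalization Adjacency normalization for diffusion: `"row"`
#'   (random walk, default) or `"symmetric"`.
#' @return An object of class `snf_config` (a named list).
#' @export
#' @examples
#' snf_config(mu = 0.5, alpha = 0.7, k_clusters = 3)
snf_config <- function(mu = 0.5, K = NULL, t_fuse = 20, alpha = 0.7,
                       diff_tol = 1e-6, k_clusters = "auto",
                       k_min = 2, k_max = 10, seed = 1L,
                       distance = NULL, rescale_smoothed = TRUE,
                       normalization = c("row", "symmetric")) {
  normalization <- match.arg(normalization)
  if (!is.numeric(mu) || mu <= 0) abort("mu must be positive")
  if (mu < 0.3 || mu > 0.8)
    warn("mu outside the recommended range [0.3, 0.8]")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    abort("alpha must lie in (0, 1)")
  if (alpha < 0.5 || alpha > 0.8)
    warn("alpha outside the recommended range [0.5, 0.8]")
  if (!is.null(K) && (K < 1)) abort("K must be >= 1")
  if (!identical(k_clusters, "auto")) {
    if (!is.numeric(k_clusters) || k_clusters < 1)
      abort("k_clusters must be 'auto' or a positive integer")
    k_clusters <- as.integer(k_clusters)
  }
  structure(
    list(mu = mu, K = K, t_fuse = as.integer(t_fuse), alpha = alpha,
         diff_tol = diff_tol, k_clusters = k_clusters,
         k_min = as.integer(k_min), k_max = as.integer(k_max),
         seed = as.integer(seed), distance = distance,
         rescale_smoothed = isTRUE(rescale_smoothed),
         normalization = normalization),
    class = "snf_config"
  )
}

#' @export
print.snf_config <- function(x, ...) {
  cat("<snf_config>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat("  ", nm, ": ", if (is.null(v)) "auto" else paste(v, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return For `read_config`, an [snf_config()]; for `write_config`, the
#'   config invisibly.
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(snf_config, vals)
}

#' @rdname read_config
#' @param config An [snf_config()] object.
#' @export
write_config <- function(config, path) {
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(config)
}

# effective neighborhood size for a cohort of n patients
resolve_K <- function(K, n) {
  if (is.null(K)) K <- max(10, round(n / 10))
  K <- as.integer(min(K, n - 1L))
  if (K < 1L) abort("K must be >= 1 and < n_patients")
  K
}
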