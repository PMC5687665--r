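# broom-style tidiers: tidy() gives per-unit rows, glance() a one-row
# summary, augment() attaches results to patient-level data.

#' Tidy a kernel pair into long form
#'
#' @param x An `snf_kernel`.
#' @param matrix Which matrix to pull: affinity `"W"`, global `"P"` or
#'   local `"S"`.
#' @param ... Unused.
#' @return Long tibble with `patient_a`, `patient_b`, `value`.
#' @export
tidy.snf_kernel <- function(x, matrix = c("W", "P", "S"), ...) {
  matrix <- match.arg(matrix)
  long_matrix(x[[matrix]], x$patient_ids, value_name = "value")
}

#' @rdname tidy.snf_kernel
#' @export
glance.snf_kernel <- function(x, ...) {
  tibble(n_patients = length(x$patient_ids), metric = x$metric,
         mu = x$mu, K = x$K,
         min_affinity = min(x$W), mean_affinity = mean(x$W))
}

#' Tidy a fused patient network
#'
#' @param x A `fused_network`.
#' @param ... Unused.
#' @return Long tibble with `patient_a`, `patient_b`, `similarity`.
#' @export
tidy.fused_network <- function(x, ...) {
  long_matrix(x$Pc, x$patient_ids, value_name = "similarity")
}

#' @rdname tidy.fused_network
#' @export
glance.fused_network <- function(x, ...) {
  off <- x$Pc
  diag(off) <- NA
  tibble(n_patients = length(x$patient_ids), n_views = x$n_views,
         t_fuse = x$t_fuse,
         mean_offdiag = mean(off, na.rm = TRUE),
         max_offdiag = max(off, na.rm = TRUE))
}

#' Tidy a spectral clustering result
#'
#' @param x An `snf_clustering`.
#' @param ... Unused.
#' @return The labels tibble (`patient_id`, `cluster`).
#' @export
tidy.snf_clustering <- function(x, ...) x$labels

#' @rdname tidy.snf_clustering
#' @export
glance.snf_clustering <- function(x, ...) {
  sizes <- table(x$labels$cluster)
  tibble(k = x$k, n_patients = nrow(x$labels),
         min_cluster_size = as.integer(min(sizes)),
         max_cluster_size = as.integer(max(sizes)),
         seed = x$seed)
}

#' Tidy a full pipeline fit
#'
#' `tidy()` returns the per-patient cluster labels; `glance()` the one-row
#' evaluation summary; `augment()` joins labels (and silhouette widths)
#' onto patient-level data.
#'
#' @param x An `snf_fit`.
#' @param ... Unused.
#' @return See description.
#' @export
tidy.snf_fit <- function(x, ...) x$clustering$labels

#' @rdname tidy.snf_fit
#' @export
glance.snf_fit <- function(x, ...) {
  dplyr::bind_cols(
    tibble(mutation_mode = x$mutation_mode, n_views = length(x$kernels)),
    x$evaluation[, setdiff(names(x$evaluation), "cluster_sizes")]
  )
}

#' @rdname tidy.snf_fit
#' @param data Patient-level data frame with a `patient_id` column;
#'   defaults to the fit's survival-free label table.
#' @export
augment.snf_fit <- function(x, data = NULL, ...) {
  lab <- x$clustering$labels
  if (x$clustering$k >= 2L) {
    sil <- silhouette_score(x$clustering, similarity_to_distance(x$fused))
    lab <- dplyr::left_join(lab, sil$scores[, c("patient_id", "silhouette")],
                            by = "patient_id")
  }
  if (is.null(data)) return(lab)
  dplyr::left_join(as_tibble(data), lab, by = "patient_id")
}

long_matrix <- function(m, ids, value_name = "value") {
  out <- tibble(
    patient_a = rep(ids, times = length(ids)),
    patient_b = rep(ids, each = length(ids)),
    value = as.vector(m)
  )
  names(out)[3] <- value_name
  out
}
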