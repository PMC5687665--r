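#' Similarity network fusion
#'
#' Merges the per-layer kernel pairs into a single patient similarity
#' network by the cross-view message-passing iteration
#' \deqn{P^{(v)} \leftarrow S^{(v)} \left(\frac{\sum_{k \ne v} P^{(k)}}{m - 1}\right) (S^{(v)})^\top}
#' run synchronously for `t_fuse` rounds over all m views; the local kernels
#' S are held fixed while the global kernels P are exchanged. After each
#' round every view is symmetrized and renormalized to the half-mass form of
#' the global kernel (off-diagonal rows summing to 1/2, diagonal 1/2) — the
#' standard stabilization without which the iteration drifts numerically.
#' The fused network is the across-view average of the final P matrices,
#' symmetrized.
#'
#' @param kernels List of two or more [affinity_kernel()] objects sharing
#'   one patient order.
#' @param t_fuse Number of fusion rounds (default 20; with `t_fuse = 0` the
#'   result is simply the symmetrized average of the input P matrices).
#' @return An object of class `fused_network`: list with `Pc` (n x n
#'   symmetric nonnegative matrix), `patient_ids`, `n_views`, `t_fuse`.
#' @export
snf_fuse <- function(kernels, t_fuse = 20) {
  check_views(kernels)
  m <- length(kernels)
  Ps <- lapply(kernels, `[[`, "P")
  Ss <- lapply(kernels, `[[`, "S")
  for (iter in seq_len(t_fuse)) {
    Ps <- fuse_round(Ps, Ss)
  }
  Pc <- Reduce(`+`, Ps) / m
  Pc <- (Pc + base::t(Pc)) / 2
  structure(
    list(Pc = Pc, patient_ids = kernels[[1]]$patient_ids,
         n_views = m, t_fuse = as.integer(t_fuse)),
    class = "fused_network"
  )
}

# one synchronous Eq-style round: update every view from the others' P
fuse_round <- function(Ps, Ss) {
  m <- length(Ps)
  new <- vector("list", m)
  for (v in seq_len(m)) {
    Pother <- Reduce(`+`, Ps[-v]) / (m - 1)
    new[[v]] <- Ss[[v]] %*% Pother %*% base::t(Ss[[v]])
  }
  lapply(new, function(P) renorm_half((P + base::t(P)) / 2))
}

# off-diagonal row mass 1/2, diagonal 1/2 (the global-kernel normal form)
renorm_half <- function(P) {
  Po <- P
  diag(Po) <- 0
  off <- rowSums(Po)
  off[off <= 0] <- 1
  P <- P / (2 * off)
  diag(P) <- 0.5
  P
}

check_views <- function(kernels) {
  if (length(kernels) < 2L) abort("fusion needs at least 2 views (m >= 2)")
  ids <- kernels[[1]]$patient_ids
  for (k in kernels) {
    if (!inherits(k, "snf_kernel")) abort("kernels must be snf_kernel objects")
    if (!identical(k$patient_ids, ids))
      abort("kernel views disagree on patient ids/order")
  }
  invisible(TRUE)
}

#' Per-round cross-view disagreement of the fusion iteration
#'
#' Runs the same iteration as [snf_fuse()] but records, after every round,
#' the largest absolute elementwise difference between any two views'
#' P matrices — a diagnostic that the views are converging toward each
#' other.
#'
#' @inheritParams snf_fuse
#' @return Tibble with columns `round` and `max_disagreement`.
#' @export
fusion_trace <- function(kernels, t_fuse = 20) {
  check_views(kernels)
  Ps <- lapply(kernels, `[[`, "P")
  Ss <- lapply(kernels, `[[`, "S")
  out <- numeric(t_fuse)
  for (iter in seq_len(t_fuse)) {
    Ps <- fuse_round(Ps, Ss)
    out[iter] <- view_disagreement(Ps)
  }
  tibble(round = seq_len(t_fuse), max_disagreement = out)
}

view_disagreement <- function(Ps) {
  m <- length(Ps)
  if (m == 1L) return(0)
  mx <- 0
  for (v in seq_len(m - 1L)) for (w in (v + 1L):m)
    mx <- max(mx, max(abs(Ps[[v]] - Ps[[w]])))
  mx
}

#' @export
print.fused_network <- function(x, ...) {
  cat("<fused_network> ", length(x$patient_ids), " patients, ",
      x$n_views, " views, ", x$t_fuse, " fusion rounds\n", sep = "")
  invisible(x)
}

#' Wrap a plain similarity matrix as a fused network
#'
#' Lets a single-view similarity matrix (or one produced outside the fusion
#' path) flow into [spectral_cluster()] and the evaluation helpers. The
#' matrix is symmetrized.
#'
#' @param Pc Square nonnegative similarity matrix with patient dimnames.
#' @param patient_ids Patient identifiers; default row names.
#' @param n_views,t_fuse Bookkeeping fields recorded on the object.
#' @return A `fused_network`.
#' @export
as_fused_network <- function(Pc, patient_ids = rownames(Pc),
                             n_views = 1L, t_fuse = 0L) {
  structure(list(Pc = (Pc + base::t(Pc)) / 2, patient_ids = patient_ids,
                 n_views = n_views, t_fuse = t_fuse),
            class = "fused_network")
}
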