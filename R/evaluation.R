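#' Turn a fused similarity network into a dissimilarity matrix
#'
#' Affine transform `d(i,j) = 1 - Pc(i,j) / max_offdiag(Pc)` with zero
#' diagonal: the most similar patient pair is at distance 0, and distance is
#' strictly decreasing in similarity, which is all the silhouette needs.
#'
#' @param fused A `fused_network`.
#' @return Symmetric nonnegative distance matrix with zero diagonal.
#' @export
similarity_to_distance <- function(fused) {
  Pc <- fused$Pc
  off <- Pc
  diag(off) <- NA
  mx <- max(off, na.rm = TRUE)
  mn <- min(off, na.rm = TRUE)
  if (mx == mn) abort("degenerate fused network: constant similarity")
  D <- 1 - Pc / mx
  diag(D) <- 0
  D <- (D + base::t(D)) / 2
  dimnames(D) <- list(fused$patient_ids, fused$patient_ids)
  D
}

#' Mean silhouette of a subtype assignment
#'
#' Standard silhouette on a precomputed dissimilarity: for each patient,
#' cohesion a(i) is the mean distance to its own cluster (excluding self)
#' and separation b(i) the smallest mean distance to another cluster;
#' s(i) = (b - a) / max(a, b), with s = 0 for singleton clusters. Values lie
#' in \[-1, 1\]; the cohort mean summarizes clustering quality.
#'
#' @param clustering An `snf_clustering`, or a tibble with `patient_id` and
#'   `cluster`.
#' @param D Symmetric dissimilarity matrix (e.g. from
#'   [similarity_to_distance()]).
#' @return List with `mean` and `scores` (tibble `patient_id`, `cluster`,
#'   `silhouette`).
#' @export
silhouette_score <- function(clustering, D) {
  labels <- assignment_labels(clustering)
  cl <- labels$cluster
  if (length(unique(cl)) < 2L)
    abort("silhouette undefined for one cluster")
  D <- D[labels$patient_id, labels$patient_id]
  sil <- cluster::silhouette(cl, dmatrix = D)
  s <- as.numeric(sil[, "sil_width"])
  list(mean = mean(s),
       scores = tibble(patient_id = labels$patient_id, cluster = cl,
                       silhouette = s))
}

#' K-sample log-rank test across subtypes
#'
#' Compares survival curves across the k subtypes with the standard
#' log-rank (Mantel-Haenszel) test: at each distinct event time, observed
#' versus expected events per group under the hypergeometric model,
#' aggregated into a chi-squared statistic with k - 1 degrees of freedom.
#' Fitted through [survival::survdiff()].
#'
#' @param clustering An `snf_clustering` or labels tibble.
#' @param survival Survival tibble (`patient_id`, `time` in days, `event`
#'   1 = death observed / 0 = censored).
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`, `n_events`.
#' @export
logrank_test <- function(clustering, survival) {
  labels <- assignment_labels(clustering)
  dat <- dplyr::inner_join(labels, survival, by = "patient_id")
  if (nrow(dat) < nrow(labels))
    abort("survival data missing for some labeled patients")
  if (length(unique(dat$cluster)) < 2L)
    abort("log-rank needs at least 2 groups")
  if (sum(dat$event) == 0L) abort("no events observed")
  fit <- survival::survdiff(survival::Surv(time, event) ~ cluster, data = dat)
  k <- length(unique(dat$cluster))
  tibble(statistic = as.numeric(fit$chisq), df = k - 1L,
         p_value = pchisq(as.numeric(fit$chisq), df = k - 1L,
                          lower.tail = FALSE),
         n = nrow(dat), n_events = sum(dat$event))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement: 1 for identical partitions,
#' about 0 for independent ones. Used to score recovery of planted subtypes
#' in simulations.
#'
#' @param labels_a,labels_b Integer/factor vectors, or tibbles with
#'   `patient_id` and `cluster` (joined on `patient_id`).
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (is.data.frame(labels_a) || is.data.frame(labels_b)) {
    a <- assignment_labels(labels_a)
    b <- assignment_labels(labels_b)
    if (!setequal(a$patient_id, b$patient_id))
      abort("partitions cover different patient sets")
    j <- dplyr::inner_join(a, b, by = "patient_id",
                           suffix = c("_a", "_b"))
    return(mclust::adjustedRandIndex(j$cluster_a, j$cluster_b))
  }
  if (length(labels_a) != length(labels_b))
    abort("partitions cover different patient sets")
  mclust::adjustedRandIndex(labels_a, labels_b)
}

# accepts snf_clustering, labels tibble, or cohort true-label tibble
assignment_labels <- function(x) {
  if (inherits(x, "snf_clustering")) return(x$labels)
  if (is.data.frame(x)) {
    nm <- names(x)
    cl_col <- intersect(c("cluster", "subtype", "label"), nm)[1]
    if (is.na(cl_col) || !"patient_id" %in% nm)
      abort("labels must have columns patient_id and cluster/subtype")
    return(tibble(patient_id = as.character(x$patient_id),
                  cluster = as.integer(as.factor(x[[cl_col]]))))
  }
  abort("cannot interpret labels object")
}

#' Evaluate a subtype assignment on a fused network
#'
#' Computes the cohort mean silhouette (on the fused-network
#' dissimilarity), the k-group log-rank test when survival data are given,
#' the adjusted Rand index when ground-truth labels are given, and the
#' per-cluster sizes.
#'
#' @param clustering An `snf_clustering`.
#' @param fused The `fused_network` that was clustered.
#' @param survival Optional survival tibble.
#' @param true_labels Optional tibble of planted subtype labels.
#' @return One-row tibble (an evaluation report): `k`, `mean_silhouette`,
#'   `logrank_statistic`, `logrank_df`, `logrank_p`, `ari`, `cluster_sizes`
#'   (list-column).
#' @export
evaluate_subtypes <- function(clustering, fused, survival = NULL,
                              true_labels = NULL) {
  sizes <- as.integer(table(clustering$labels$cluster))
  sil <- if (clustering$k >= 2L)
    silhouette_score(clustering, similarity_to_distance(fused))$mean
  else NA_real_
  lr <- if (!is.null(survival) && clustering$k >= 2L)
    logrank_test(clustering, survival)
  else tibble(statistic = NA_real_, df = NA_integer_, p_value = NA_real_)
  ari <- if (!is.null(true_labels))
    adjusted_rand_index(clustering$labels, true_labels)
  else NA_real_
  tibble(k = clustering$k,
         mean_silhouette = sil,
         logrank_statistic = lr$statistic[1],
         logrank_df = lr$df[1],
         logrank_p = lr$p_value[1],
         ari = ari,
         cluster_sizes = list(sizes))
}

#' Compare pipelines with and without (smoothed) mutation data
#'
#' Reproduces the method-comparison harness on one cohort by running three
#' pipelines that differ only in how the mutation layer enters:
#' \describe{
#'   \item{`continuous`}{continuous layers only (no mutation data);}
#'   \item{`raw_mutations`}{continuous layers plus the raw binary mutation
#'     matrix compared with the chi-squared distance;}
#'   \item{`smoothed_mutations`}{continuous layers plus the
#'     network-diffusion-smoothed mutation profiles compared with the
#'     Euclidean distance (the full method).}
#' }
#' Each pipeline fuses its layers, clusters the fused network, and is
#' scored by mean silhouette, log-rank p-value and (when planted labels
#' exist) adjusted Rand index.
#'
#' @param cohort An `snf_cohort` (see [as_snf_cohort()] or
#'   [generate_cohort()]).
#' @param config An [snf_config()].
#' @param methods Subset of the three method names to run.
#' @return Tibble with one row per method: `method`, `k`,
#'   `mean_silhouette`, `logrank_p`, `ari`.
#' @export
compare_methods <- function(cohort, config = snf_config(),
                            methods = c("continuous", "raw_mutations",
                                        "smoothed_mutations")) {
  methods <- match.arg(methods, several.ok = TRUE)
  needs_mut <- setdiff(methods, "continuous")
  if (length(needs_mut) > 0 && is.null(cohort$mutations))
    abort(paste0("mutation layer required for method(s): ",
                 paste(needs_mut, collapse = ", ")))
  rows <- purrr::map(methods, function(mode) {
    fit <- run_pipeline(cohort, config, mutation_mode = switch(
      mode, continuous = "none", raw_mutations = "raw",
      smoothed_mutations = "smoothed"))
    ev <- fit$evaluation
    tibble(method = mode, k = ev$k, mean_silhouette = ev$mean_silhouette,
           logrank_p = ev$logrank_p, ari = ev$ari)
  })
  dplyr::bind_rows(rows)
}
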