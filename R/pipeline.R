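#' Assemble a cohort from its components
#'
#' Validates and aligns continuous layers, an optional binary mutation
#' layer, an optional gene network and an optional survival table into the
#' `snf_cohort` container the pipeline consumes. All components are
#' restricted to the common patients in canonical (sorted) order via
#' [align_cohort()].
#'
#' @param layers Named list of continuous feature tibbles.
#' @param mutations Optional binary feature tibble of mutation calls.
#' @param network Optional [gene_network()] (required for diffusion
#'   smoothing).
#' @param survival Optional survival tibble.
#' @param true_labels Optional tibble of known subtype labels
#'   (`patient_id`, `subtype`) for benchmarking.
#' @return An `snf_cohort`.
#' @export
as_snf_cohort <- function(layers, mutations = NULL, network = NULL,
                          survival = NULL, true_labels = NULL) {
  if (is.data.frame(layers)) layers <- list(layer1 = layers)
  if (is.null(names(layers)) || any(!nzchar(names(layers))))
    names(layers) <- paste0("layer", seq_along(layers))
  all_layers <- layers
  if (!is.null(mutations)) all_layers <- c(all_layers, list(.mut = mutations))
  al <- align_cohort(all_layers, survival)
  mutations <- al$layers[[".mut"]]
  layers <- al$layers[setdiff(names(al$layers), ".mut")]
  if (!is.null(true_labels)) {
    lab <- planted_labels(true_labels)
    ids <- layers[[1]]$patient_id
    true_labels <- lab[match(ids, lab$patient_id), , drop = FALSE]
    if (anyNA(true_labels$subtype)) abort("true_labels missing some patients")
  }
  structure(list(layers = layers, mutations = mutations, network = network,
                 survival = al$survival, true_labels = true_labels,
                 params = NULL),
            class = "snf_cohort")
}

#' Run the full subtyping pipeline
#'
#' Executes the complete method on a cohort: (1) smooth the binary mutation
#' layer over the gene network by diffusion (unless `mutation_mode`
#' disables it), (2) build a kernel pair per layer with the scaled
#' exponential kernel, (3) fuse all views by similarity network fusion,
#' (4) spectral-cluster the fused network, and (5) evaluate the assignment
#' (silhouette, log-rank, ARI against planted truth when available).
#'
#' Continuous layers use the Euclidean distance on feature-standardized
#' values; smoothed mutation profiles use the Euclidean distance without
#' standardization; raw binary mutations use the chi-squared distance.
#'
#' @param cohort An `snf_cohort` (from [as_snf_cohort()] or
#'   [generate_cohort()]).
#' @param config An [snf_config()].
#' @param mutation_mode How the mutation layer enters: `"smoothed"`
#'   (diffusion over the network; the full method), `"raw"` (binary matrix
#'   with chi-squared distance, no network needed), or `"none"`.
#' @param outdir Optional directory; when given, cluster labels
#'   (`labels.tsv`), the fused matrix (`fused.tsv`) and a JSON run report
#'   (`report.json`) are written there.
#' @return An object of class `snf_fit`: list with `clustering`, `fused`,
#'   `kernels`, `smoothed` (or `NULL`), `evaluation` (one-row tibble),
#'   `config`, `mutation_mode`, `timings` (named seconds) and, when
#'   `outdir` was given, `files`.
#' @export
#' @examples
#' co <- generate_cohort(seed = 7, n_patients = 40, n_genes = 120)
#' fit <- run_pipeline(co, snf_config(k_clusters = 3, t_fuse = 10))
#' glance(fit)
run_pipeline <- function(cohort, config = snf_config(),
                         mutation_mode = c("smoothed", "raw", "none"),
                         outdir = NULL) {
  mutation_mode <- match.arg(mutation_mode)
  if (!inherits(cohort, "snf_cohort")) abort("cohort must be an snf_cohort")
  if (length(cohort$layers) == 0 && mutation_mode == "none")
    abort("no layers to analyse")
  timings <- c()
  tic <- function(expr, stage) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      abort(paste0("stage '", stage, "': ", conditionMessage(e))))
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  smoothed <- NULL
  views <- cohort$layers
  metrics <- setNames(rep("euclidean", length(views)), names(views))
  standardize <- setNames(rep(TRUE, length(views)), names(views))
  if (mutation_mode != "none") {
    if (is.null(cohort$mutations))
      abort("mutation layer required for this mutation_mode")
    if (mutation_mode == "smoothed") {
      if (is.null(cohort$network)) abort("network required for diffusion")
      smoothed <- tic(network_smooth(
        cohort$mutations, cohort$network, alpha = config$alpha,
        tol = config$diff_tol, rescale = config$rescale_smoothed,
        normalization = config$normalization), "diffusion")
      views <- c(views, list(mutation_smoothed = smoothed))
      metrics <- c(metrics, mutation_smoothed = "euclidean")
      standardize <- c(standardize, mutation_smoothed = FALSE)
    } else {
      views <- c(views, list(mutation_raw = cohort$mutations))
      metrics <- c(metrics, mutation_raw = "chi_squared")
      standardize <- c(standardize, mutation_raw = FALSE)
    }
  }
  # per-layer distance overrides from the config
  if (!is.null(config$distance)) {
    for (nm in names(config$distance))
      if (nm %in% names(metrics)) metrics[[nm]] <- config$distance[[nm]]
  }

  kernels <- tic(purrr::imap(views, function(v, nm) {
    affinity_kernel(v, metric = metrics[[nm]], mu = config$mu, K = config$K,
                    standardize = standardize[[nm]])
  }), "affinity")

  fused <- tic({
    if (length(kernels) >= 2L) {
      snf_fuse(kernels, t_fuse = config$t_fuse)
    } else {
      # single view: no fusion partner, cluster its global kernel directly
      as_fused_network(kernels[[1]]$P, kernels[[1]]$patient_ids)
    }
  }, "fusion")

  clustering <- tic(spectral_cluster(
    fused, k = config$k_clusters, seed = config$seed,
    k_min = config$k_min, k_max = config$k_max), "clustering")

  evaluation <- tic(evaluate_subtypes(
    clustering, fused, survival = cohort$survival,
    true_labels = cohort$true_labels), "evaluation")

  fit <- structure(
    list(clustering = clustering, fused = fused, kernels = kernels,
         smoothed = smoothed, evaluation = evaluation, config = config,
         mutation_mode = mutation_mode, timings = unlist(timings),
         version = as.character(utils::packageVersion("ndsnf"))),
    class = "snf_fit"
  )
  if (!is.null(outdir)) fit$files <- write_fit(fit, outdir)
  fit
}

# labels + fused matrix + JSON report; byte-stable given config and seed
write_fit <- function(fit, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  labf <- file.path(outdir, "labels.tsv")
  write_labels(fit$clustering$labels, labf)
  fusf <- file.path(outdir, "fused.tsv")
  write_feature_table(ft_tibble(fit$fused$Pc), fusf)
  repf <- file.path(outdir, "report.json")
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    cfg <- unclass(fit$config)
    cfg <- cfg[!vapply(cfg, is.null, logical(1))]
    report <- list(
      version = fit$version,
      mutation_mode = fit$mutation_mode,
      config = cfg,
      seed = fit$config$seed,
      timings_sec = as.list(round(fit$timings, 4)),
      evaluation = as.list(fit$evaluation[
        , setdiff(names(fit$evaluation), "cluster_sizes")]),
      cluster_sizes = fit$evaluation$cluster_sizes[[1]],
      files = list(labels = basename(labf), fused = basename(fusf))
    )
    jsonlite::write_json(report, repf, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    repf <- NULL
  }
  c(labels = labf, fused = fusf, report = repf)
}

#' @export
print.snf_fit <- function(x, ...) {
  ev <- x$evaluation
  cat("<snf_fit> ", length(x$fused$patient_ids), " patients, ",
      length(x$kernels), " view(s), mutation_mode = ", x$mutation_mode,
      "\n  k = ", ev$k,
      "; mean silhouette = ", signif(ev$mean_silhouette, 3),
      "; log-rank p = ", signif(ev$logrank_p, 3),
      if (!is.na(ev$ari)) paste0("; ARI vs planted = ", signif(ev$ari, 3)),
      "\n", sep = "")
  invisible(x)
}
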