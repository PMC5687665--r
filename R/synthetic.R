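# Synthetic cohorts with planted subtype structure.
#
# The generator emulates the kind of multi-omic TCGA cohort the method is
# aimed at: a modular gene interaction network (stochastic block model), a
# very sparse binary mutation matrix whose subtype signal is carried by
# *module membership* rather than shared genes, continuous omics layers
# with subtype-shifted means, and subtype-dependent exponential survival.
# All randomness flows through a single seed so cohorts are bit-reproducible.

#' Generate a modular gene interaction network
#'
#' Stochastic-block-model graph whose modules act as subtype-specific
#' driver pathways: edges appear with probability `p_within` inside a
#' module and `p_between` across modules.
#'
#' @param n_genes Number of genes.
#' @param k_modules Number of (equal-sized) modules.
#' @param p_within,p_between Edge probabilities inside / across modules
#'   (`p_within > p_between` gives usable module structure).
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A [gene_network()] with a `modules` assignment.
#' @export
generate_network <- function(n_genes = 500, k_modules = 5,
                             p_within = 0.3, p_between = 0.01,
                             seed = NULL) {
  if (any(c(p_within, p_between) < 0 | c(p_within, p_between) > 1))
    abort("edge probabilities must lie in [0, 1]")
  sizes <- rep(n_genes %/% k_modules, k_modules)
  sizes[seq_len(n_genes %% k_modules)] <- sizes[seq_len(n_genes %% k_modules)] + 1L
  if (any(sizes == 0)) abort("module of size 0; reduce k_modules")
  pref <- matrix(p_between, k_modules, k_modules)
  diag(pref) <- p_within
  g <- with_opt_seed(seed, igraph::sample_sbm(n_genes, pref.matrix = pref,
                                              block.sizes = sizes))
  genes <- sprintf("g%04d", seq_len(n_genes))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- tibble(from = genes[el[, 1]], to = genes[el[, 2]], weight = 1)
  modules <- setNames(rep(seq_len(k_modules), sizes), genes)
  gene_network(edges, gene_ids = genes, modules = modules)
}

#' Generate a sparse binary mutation matrix with network-mediated signal
#'
#' Each patient receives `Poisson(lambda)` mutations; a binomial
#' `driver_fraction` share is drawn uniformly from the patient's subtype
#' driver module, the remainder uniformly from all genes. Because driver
#' mutations are spread across a whole module, two patients of the same
#' subtype typically share few or no mutated genes — the subtype signal is
#' only recoverable through the network.
#'
#' @param labels Tibble with `patient_id` and `subtype` (1..k), or an
#'   integer vector.
#' @param network A [generate_network()] result (needs `modules`); subtype
#'   s uses module s as its driver module.
#' @param lambda Mean mutations per patient (Poisson).
#' @param driver_fraction Expected share of a patient's mutations falling
#'   in its driver module.
#' @param seed Optional integer seed.
#' @return Binary feature tibble over all network genes.
#' @export
generate_mutations <- function(labels, network, lambda = 8,
                               driver_fraction = 0.8, seed = NULL) {
  if (lambda <= 0) abort("lambda must be positive")
  lab <- planted_labels(labels)
  if (is.null(network$modules)) abort("network has no module assignment")
  k <- max(lab$subtype)
  if (k > max(network$modules))
    abort("more subtypes than network modules")
  genes <- network$gene_ids
  with_opt_seed(seed, {
    M <- matrix(0, nrow(lab), length(genes),
                dimnames = list(lab$patient_id, genes))
    for (i in seq_len(nrow(lab))) {
      m <- rpois(1, lambda)
      if (m == 0) next
      nd <- rbinom(1, m, driver_fraction)
      module_genes <- genes[network$modules == lab$subtype[i]]
      picks <- c(sample(module_genes, min(nd, length(module_genes))),
                 sample(genes, m - nd))
      M[i, picks] <- 1
    }
    ft_tibble(M, dtype = "binary")
  })
}

#' Generate a continuous omics layer with subtype-shifted means
#'
#' For each subtype a random 10% of features are informative, shifted by
#' `+/- delta` (random sign); Gaussian noise with standard deviation
#' `sigma` is added everywhere.
#'
#' @param labels Planted subtype labels (tibble or integer vector).
#' @param n_features Number of features.
#' @param delta Mean shift on informative features (effect size).
#' @param sigma Noise standard deviation.
#' @param prefix Feature-name prefix (layers get distinct names).
#' @param seed Optional integer seed.
#' @return Continuous feature tibble.
#' @export
generate_continuous <- function(labels, n_features = 200, delta = 1,
                                sigma = 1, prefix = "f", seed = NULL) {
  if (delta < 0) abort("delta must be >= 0")
  if (sigma <= 0) abort("sigma must be positive")
  lab <- planted_labels(labels)
  k <- max(lab$subtype)
  n_inf <- max(1L, round(0.1 * n_features))
  with_opt_seed(seed, {
    means <- matrix(0, k, n_features)
    for (s in seq_len(k)) {
      idx <- sample(n_features, n_inf)
      means[s, idx] <- sample(c(-delta, delta), n_inf, replace = TRUE)
    }
    X <- means[lab$subtype, , drop = FALSE] +
      matrix(rnorm(nrow(lab) * n_features, sd = sigma), nrow(lab))
    dimnames(X) <- list(lab$patient_id,
                        sprintf("%s%03d", prefix, seq_len(n_features)))
    ft_tibble(X, dtype = "continuous")
  })
}

#' Generate subtype-dependent survival data
#'
#' Exponential event times with per-subtype hazard
#' `base_hazard * hazard_ratios[subtype]` and independent exponential
#' censoring at rate `censor_rate`; observed time is the earlier of the
#' two, with the event indicator recording which.
#'
#' @param labels Planted subtype labels.
#' @param base_hazard Baseline hazard per day (default 1/1000: median
#'   survival around two years for the reference subtype).
#' @param hazard_ratios Positive vector, one entry per subtype.
#' @param censor_rate Exponential censoring rate per day; 0 disables
#'   censoring.
#' @param seed Optional integer seed.
#' @return Survival tibble (`patient_id`, `time`, `event`).
#' @export
generate_survival <- function(labels, base_hazard = 1 / 1000,
                              hazard_ratios = c(1, 2, 4),
                              censor_rate = 1.5e-4, seed = NULL) {
  lab <- planted_labels(labels)
  k <- max(lab$subtype)
  if (length(hazard_ratios) != k || any(hazard_ratios <= 0))
    abort("hazard_ratios must be positive, one per subtype")
  with_opt_seed(seed, {
    n <- nrow(lab)
    ev <- rexp(n, rate = base_hazard * hazard_ratios[lab$subtype])
    cs <- if (censor_rate > 0) rexp(n, rate = censor_rate) else rep(Inf, n)
    tibble(patient_id = lab$patient_id,
           time = pmin(ev, cs),
           event = as.integer(ev <= cs))
  })
}

#' Generate a complete synthetic multi-omic cohort
#'
#' One call builds every input the pipeline needs with planted truth: the
#' gene network, three continuous layers (methylation/mRNA/miRNA
#' stand-ins), the sparse mutation matrix and the survival table. The
#' `"benchmark-v1"` scenario freezes all parameters at the package's
#' reference study conditions (n = 100 patients, k = 3 subtypes, 500 genes
#' in 5 modules, Poisson(8) mutations with driver fraction 0.8, 200-feature
#' continuous layers with delta = 1 / sigma = 1, hazard ratios 1/2/4).
#'
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of it.
#' @param scenario Currently `"benchmark-v1"`.
#' @param ... Named overrides of scenario parameters (`n_patients`, `k`,
#'   `n_genes`, `k_modules`, `p_within`, `p_between`, `lambda`,
#'   `driver_fraction`, `n_layers`, `n_features`, `delta`, `sigma`,
#'   `base_hazard`, `hazard_ratios`, `censor_rate`).
#' @return An `snf_cohort`: list with `layers` (named list of continuous
#'   feature tibbles), `mutations`, `network`, `survival`, `true_labels`
#'   (tibble `patient_id`, `subtype`) and `params`.
#' @export
#' @examples
#' co <- generate_cohort(seed = 7)
#' names(co$layers)
generate_cohort <- function(seed = 1L, scenario = "benchmark-v1", ...) {
  if (!identical(scenario, "benchmark-v1"))
    abort(paste0("unknown scenario '", scenario, "'"))
  params <- modifyList(benchmark_v1_params(), list(...))
  if (length(params$hazard_ratios) != params$k)
    params$hazard_ratios <- rescale_hr(params$hazard_ratios, params$k)
  withr::with_seed(as.integer(seed), {
    n <- params$n_patients
    ids <- sprintf("P%03d", seq_len(n))
    subtype <- rep(seq_len(params$k), length.out = n)
    labels <- tibble(patient_id = ids, subtype = subtype)
    network <- generate_network(params$n_genes, params$k_modules,
                                params$p_within, params$p_between)
    layers <- lapply(seq_len(params$n_layers), function(l) {
      generate_continuous(labels, params$n_features, params$delta,
                          params$sigma, prefix = paste0("L", l, "_"))
    })
    names(layers) <- paste0("layer", seq_len(params$n_layers))
    mutations <- generate_mutations(labels, network, params$lambda,
                                    params$driver_fraction)
    surv <- generate_survival(labels, params$base_hazard,
                              params$hazard_ratios, params$censor_rate)
    structure(
      list(layers = layers, mutations = mutations, network = network,
           survival = surv, true_labels = labels,
           params = c(params, list(rng_seed = as.integer(seed),
                                   scenario = scenario))),
      class = "snf_cohort"
    )
  })
}

benchmark_v1_params <- function() {
  list(n_patients = 100L, k = 3L, n_genes = 500L, k_modules = 5L,
       p_within = 0.3, p_between = 0.01, lambda = 8, driver_fraction = 0.8,
       n_layers = 3L, n_features = 200L, delta = 1, sigma = 1,
       base_hazard = 1 / 1000, hazard_ratios = c(1, 2, 4),
       censor_rate = 1.5e-4)
}

# pad/trim hazard ratios when k is overridden: geometric spacing by 2
rescale_hr <- function(hr, k) {
  if (length(hr) >= k) return(hr[seq_len(k)])
  2^(seq_len(k) - 1)
}

planted_labels <- function(labels) {
  if (is.data.frame(labels)) {
    if (!all(c("patient_id", "subtype") %in% names(labels)))
      abort("labels tibble needs columns patient_id and subtype")
    return(tibble(patient_id = as.character(labels$patient_id),
                  subtype = as.integer(labels$subtype)))
  }
  tibble(patient_id = sprintf("P%03d", seq_along(labels)),
         subtype = as.integer(labels))
}

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' @export
print.snf_cohort <- function(x, ...) {
  cat("<snf_cohort> ", nrow(x$true_labels), " patients, ",
      length(x$layers), " continuous layer(s), ",
      if (!is.null(x$mutations)) paste0(ncol(x$mutations) - 1L,
                                        "-gene mutation layer, "),
      length(x$network$gene_ids), "-gene network\n", sep = "")
  invisible(x)
}

#' Write a synthetic cohort to a directory of standard files
#'
#' Writes each layer, the mutation matrix, the network edge list, the
#' survival table and the planted labels as TSV files, so the file-based
#' entry points (and the command-line interface) can be exercised.
#'
#' @param cohort An `snf_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a character vector of the files written.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (nm in names(cohort$layers)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_feature_table(cohort$layers[[nm]], p)
    files <- c(files, p)
  }
  if (!is.null(cohort$mutations)) {
    p <- file.path(dir, "mutations.tsv")
    write_feature_table(cohort$mutations, p)
    files <- c(files, p)
  }
  if (!is.null(cohort$network)) {
    p <- file.path(dir, "network.tsv")
    write_gene_network(cohort$network, p)
    files <- c(files, p)
  }
  if (!is.null(cohort$survival)) {
    p <- file.path(dir, "survival.tsv")
    write_survival_table(cohort$survival, p)
    files <- c(files, p)
  }
  if (!is.null(cohort$true_labels)) {
    p <- file.path(dir, "true_labels.tsv")
    readr::write_tsv(cohort$true_labels, p, progress = FALSE)
    files <- c(files, p)
  }
  invisible(files)
}
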