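#' Read a patient-by-feature table
#'
#' Reads a delimited text matrix (TSV canonical; comma detected automatically)
#' whose first column holds patient identifiers and whose header row holds
#' feature identifiers (gene symbols for mutation data). Values are validated
#' against the declared data type: binary tables may contain only 0/1, and
#' continuous tables must be finite throughout.
#'
#' @param path Path to the delimited text file.
#' @param dtype `"continuous"` or `"binary"` (mutation status).
#' @param transpose If `TRUE` the file is features-by-patients and is
#'   transposed after reading, so that patients are rows in memory.
#' @return A tibble whose first column is `patient_id`, one row per patient
#'   and one numeric column per feature, with attribute `dtype`.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("patient_id\tTP53\tPIK3CA", "P1\t1\t0", "P2\t0\t1"), tf)
#' read_feature_table(tf, dtype = "binary")
read_feature_table <- function(path, dtype = c("continuous", "binary"),
                               transpose = FALSE) {
  dtype <- match.arg(dtype)
  delim <- sniff_delim(path)
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(tbl) == 0L) abort(paste0("no data rows in '", path, "'"))
  if (transpose) {
    m <- as.matrix(tbl[, -1, drop = FALSE])
    rownames(m) <- as.character(tbl[[1]])
    m <- base::t(m)
    tbl <- dplyr::bind_cols(tibble(patient_id = rownames(m)), as_tibble(m))
  }
  names(tbl)[1] <- "patient_id"
  tbl$patient_id <- as.character(tbl$patient_id)
  validate_feature_tbl(tbl, dtype)
}

#' Write a patient-by-feature table to TSV
#'
#' @param tbl Feature tibble (first column `patient_id`).
#' @param path Output path.
#' @return `tbl`, invisibly.
#' @export
write_feature_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(tbl)
}

# Validates shape, id uniqueness and value domain; attaches the dtype attr.
validate_feature_tbl <- function(tbl, dtype) {
  if (anyDuplicated(tbl$patient_id))
    abort("duplicate patient_ids in feature table")
  feats <- names(tbl)[-1]
  if (length(feats) == 0L) abort("no feature columns")
  if (anyDuplicated(feats)) abort("duplicate feature_ids in feature table")
  m <- ft_matrix(tbl)
  if (!is.numeric(m)) abort("non-numeric values in feature table")
  if (dtype == "binary") {
    if (anyNA(m) || !all(m %in% c(0, 1)))
      abort("non-binary entry in binary feature table")
  } else {
    if (anyNA(m) || any(!is.finite(m)))
      abort("non-finite value in continuous feature table")
  }
  attr(tbl, "dtype") <- dtype
  tbl
}

# tibble (patient_id + features) -> numeric matrix with patient rownames
ft_matrix <- function(tbl) {
  m <- as.matrix(tbl[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tbl$patient_id
  m
}

# numeric matrix with rownames -> feature tibble
ft_tibble <- function(m, dtype = "continuous") {
  tbl <- dplyr::bind_cols(tibble(patient_id = rownames(m)), as_tibble(m))
  attr(tbl, "dtype") <- dtype
  tbl
}

sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) abort(paste0("no data rows in '", path, "'"))
  if (grepl("\t", first)) "\t" else ","
}

#' Construct a gene interaction network
#'
#' @param edges Tibble or data frame with columns `from`, `to` and optionally
#'   `weight` (positive). Edges are undirected; duplicates (in either
#'   orientation) are collapsed and self-loops dropped with a message.
#' @param gene_ids Optional character vector of node ids; defaults to all ids
#'   seen in `edges`. Extra ids become isolated genes.
#' @param modules Optional named integer vector mapping gene id to module,
#'   used by the synthetic cohort generator.
#' @return An object of class `gene_network`.
#' @export
gene_network <- function(edges, gene_ids = NULL, modules = NULL) {
  edges <- as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges)))
    abort("edges must have columns 'from' and 'to'")
  if (!"weight" %in% names(edges)) edges$weight <- 1
  if (any(!is.finite(edges$weight) | edges$weight < 0))
    abort("negative or non-finite edge weight")
  self <- edges$from == edges$to
  if (any(self)) {
    inform(paste0("dropped ", sum(self), " self-loop(s)"))
    edges <- edges[!self, , drop = FALSE]
  }
  # canonical orientation so (a,b) and (b,a) collapse to one undirected edge
  lo <- pmin(edges$from, edges$to)
  hi <- pmax(edges$from, edges$to)
  edges <- dplyr::distinct(
    tibble(from = lo, to = hi, weight = edges$weight),
    .data$from, .data$to, .keep_all = TRUE
  )
  gene_ids <- gene_ids %||% sort(unique(c(edges$from, edges$to)))
  missing <- setdiff(unique(c(edges$from, edges$to)), gene_ids)
  if (length(missing) > 0)
    abort("edge endpoints absent from gene_ids")
  structure(
    list(gene_ids = gene_ids, edges = edges, modules = modules),
    class = "gene_network"
  )
}

#' @export
print.gene_network <- function(x, ...) {
  cat("<gene_network> ", length(x$gene_ids), " genes, ",
      nrow(x$edges), " undirected edges",
      if (!is.null(x$modules)) paste0(", ", length(unique(x$modules)),
                                      " modules"), "\n", sep = "")
  invisible(x)
}

#' Read a gene interaction network from an edge list
#'
#' Accepts a two-column whitespace/tab-separated edge list
#' (`geneA geneB`), a weighted three-column list (`geneA geneB weight`), or
#' the SIF dialect (`geneA relation geneB`, detected when the third column is
#' non-numeric). Self-loops are dropped, duplicate edges collapsed.
#'
#' @param path Path to the edge-list file.
#' @return A [gene_network()] object.
#' @export
read_gene_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort(paste0("no edges in '", path, "'"))
  parts <- strsplit(trimws(lines), "[\t ]+")
  nf <- lengths(parts)
  if (any(nf < 2L | nf > 3L))
    abort(paste0("malformed line in '", path, "': '",
                 lines[which(nf < 2L | nf > 3L)[1]], "'"))
  third <- vapply(parts, function(p) if (length(p) == 3L) p[3] else NA_character_,
                  character(1))
  # SIF dialect: relation in column 2, second gene in (non-numeric) column 3
  is_sif <- all(nf == 3L) && all(is.na(suppressWarnings(as.numeric(third))))
  from <- vapply(parts, `[`, character(1), 1L)
  if (is_sif) {
    to <- third
    weight <- rep(1, length(parts))
  } else {
    to <- vapply(parts, `[`, character(1), 2L)
    weight <- ifelse(nf == 3L, suppressWarnings(as.numeric(third)), 1)
    if (anyNA(weight))
      abort(paste0("malformed weight in '", path, "'"))
  }
  gene_network(tibble(from = from, to = to, weight = weight))
}

#' Write a gene network as a TSV edge list
#' @param network A [gene_network()].
#' @param path Output path.
#' @return `network`, invisibly.
#' @export
write_gene_network <- function(network, path) {
  readr::write_tsv(network$edges, path, col_names = FALSE, progress = FALSE)
  invisible(network)
}

#' Read a patient survival table
#'
#' Expects a TSV/CSV with header `patient_id`, one or more follow-up time
#' columns (in days) and `event` (1 = death observed, 0 = censored). When
#' several time columns are supplied (e.g. days to death and days to last
#' known alive), the per-patient maximum of the available values is used.
#'
#' @param path Path to the table.
#' @param time_cols Names of the follow-up time column(s). Default `"time"`.
#' @return Tibble with columns `patient_id`, `time`, `event`.
#' @export
read_survival_table <- function(path, time_cols = "time") {
  delim <- sniff_delim(path)
  tbl <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!all(c("patient_id", time_cols, "event") %in% names(tbl)))
    abort("survival table must have columns patient_id, time column(s), event")
  time <- do.call(pmax, c(unname(tbl[time_cols]), list(na.rm = TRUE)))
  out <- tibble(patient_id = as.character(tbl$patient_id),
                time = as.numeric(time),
                event = as.integer(tbl$event))
  validate_survival_tbl(out)
}

validate_survival_tbl <- function(tbl) {
  if (anyDuplicated(tbl$patient_id)) abort("duplicate patient_ids in survival table")
  if (any(!is.finite(tbl$time)) || any(tbl$time < 0))
    abort("survival times must be nonnegative and finite")
  if (!all(tbl$event %in% c(0L, 1L))) abort("event must be 0/1")
  tbl
}

#' Write a survival table to TSV
#' @param tbl Survival tibble.
#' @param path Output path.
#' @return `tbl`, invisibly.
#' @export
write_survival_table <- function(tbl, path) {
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(tbl)
}

#' Restrict all cohort components to the common patients
#'
#' Intersects the patient ids of every layer (and the survival table, if
#' given) and reorders all components to one canonical, lexicographically
#' sorted patient order, so downstream results do not depend on input file
#' order. Patients missing from any component are dropped and reported.
#'
#' @param layers Named list of feature tibbles.
#' @param survival Optional survival tibble.
#' @return List with elements `layers`, `survival` and `dropped` (character
#'   vector of patient ids removed from at least one component).
#' @export
align_cohort <- function(layers, survival = NULL) {
  if (length(layers) < 1L) abort("need at least one layer")
  idsets <- lapply(layers, function(l) l$patient_id)
  if (!is.null(survival)) idsets <- c(idsets, list(survival$patient_id))
  common <- Reduce(intersect, idsets)
  if (length(common) == 0L) abort("empty patient intersection across inputs")
  common <- sort(common)
  dropped <- sort(setdiff(unique(unlist(idsets)), common))
  if (length(dropped) > 0)
    inform(paste0("align_cohort: dropped ", length(dropped),
                  " patient(s) absent from at least one input"))
  layers <- lapply(layers, function(l) {
    out <- l[match(common, l$patient_id), , drop = FALSE]
    attr(out, "dtype") <- attr(l, "dtype")
    out
  })
  if (!is.null(survival))
    survival <- survival[match(common, survival$patient_id), , drop = FALSE]
  list(layers = layers, survival = survival, dropped = dropped)
}

#' Write cluster labels to TSV
#' @param labels Tibble with columns `patient_id` and `cluster`.
#' @param path Output path.
#' @return `labels`, invisibly.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels, path, progress = FALSE)
  invisible(labels)
}
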