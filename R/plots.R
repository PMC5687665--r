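# ggplot2 displays for the main result types.

#' Heatmap of a fused patient network
#'
#' Patients are ordered by cluster (when a clustering is supplied) so the
#' block structure of the fused similarity is visible.
#'
#' @param object A `fused_network`.
#' @param clustering Optional `snf_clustering` used to order patients.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fused_network <- function(object, clustering = NULL, ...) {
  ord <- object$patient_ids
  if (!is.null(clustering))
    ord <- clustering$labels$patient_id[order(clustering$labels$cluster)]
  df <- tidy(object)
  df$patient_a <- factor(df$patient_a, levels = ord)
  df$patient_b <- factor(df$patient_b, levels = ord)
  ggplot2::ggplot(df, ggplot2::aes(.data$patient_a, .data$patient_b,
                                   fill = .data$similarity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity",
                  title = "Fused patient similarity network") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Laplacian eigenvalue scree with the chosen k
#'
#' @param object An `snf_clustering`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snf_clustering <- function(object, ...) {
  df <- tibble(index = seq_along(object$eigenvalues),
               eigenvalue = object$eigenvalues)
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linetype = "dotted") +
    ggplot2::geom_vline(xintercept = object$k + 0.5, colour = "red",
                        linetype = "dashed") +
    ggplot2::labs(x = "eigenvalue index",
                  y = "normalized Laplacian eigenvalue",
                  title = paste0("Eigengap selection: k = ", object$k)) +
    ggplot2::theme_minimal()
}

#' Kaplan-Meier curves by subtype
#'
#' Estimates one Kaplan-Meier survival curve per cluster and draws them
#' with the log-rank p-value in the subtitle.
#'
#' @param clustering An `snf_clustering` (or labels tibble).
#' @param survival Survival tibble (`patient_id`, `time`, `event`).
#' @return A ggplot object.
#' @export
plot_survival_curves <- function(clustering, survival) {
  labels <- assignment_labels(clustering)
  df <- dplyr::inner_join(labels, survival, by = "patient_id")
  fit <- survival::survfit(survival::Surv(time, event) ~ cluster, data = df)
  strata <- rep(names(fit$strata), fit$strata)
  km <- tibble(time = fit$time, surv = fit$surv,
               cluster = sub("^cluster=", "", strata))
  lr <- logrank_test(labels, survival)
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$cluster)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "days", y = "survival probability", colour = "subtype",
                  title = "Survival by subtype",
                  subtitle = paste0("log-rank p = ",
                                    signif(lr$p_value, 3))) +
    ggplot2::theme_minimal()
}

#' Cross-view disagreement over fusion rounds
#'
#' @param trace Tibble from [fusion_trace()].
#' @return A ggplot object.
#' @export
plot_fusion_trace <- function(trace) {
  ggplot2::ggplot(trace, ggplot2::aes(.data$round,
                                      .data$max_disagreement)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "fusion round", y = "max cross-view disagreement",
                  title = "Convergence of the fusion iteration") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
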