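# ggplot2 views of the result objects

#' Plot enterotype separation in PCoA space
#'
#' Scatter of the first two principal coordinates, optionally colored by
#' enterotype.
#'
#' @param object An `enterotype_pcoa`.
#' @param labels Optional labels tibble (`sample_id`, `enterotype`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enterotype_pcoa <- function(object, labels = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) abort("need at least two retained axes to plot")
  if (!is.null(labels)) {
    lab <- as_label_vector(labels)
    df$enterotype <- factor(paste0("ET", lab[df$sample_id]))
  }
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$Axis1, y = .data$Axis2)) +
    ggplot2::labs(
      x = sprintf("PCo1 (%.1f%%)", 100 * object$proportion_explained[1]),
      y = sprintf("PCo2 (%.1f%%)", 100 * object$proportion_explained[2])
    ) +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    p + ggplot2::geom_point(ggplot2::aes(color = .data$enterotype), size = 2)
  } else {
    p + ggplot2::geom_point(size = 2)
  }
}

#' @rdname autoplot.enterotype_pcoa
#' @param ordination An `enterotype_pcoa`.
#' @export
plot_ordination <- function(ordination, labels = NULL) {
  autoplot.enterotype_pcoa(ordination, labels = labels)
}

#' Plot the k-selection profile
#'
#' Silhouette index and mean prediction strength against the candidate
#' number of clusters, with the PS acceptance threshold and the chosen k
#' marked.
#'
#' @param object A `k_selection` from [choose_k()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.k_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(object$summary,
                              c("silhouette", "prediction_strength"),
                              names_to = "criterion", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value,
                                     color = .data$criterion)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$ps_threshold, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$chosen_k, linetype = "dotted") +
    ggplot2::labs(x = "number of clusters k", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.k_selection
#' @param report A `k_selection`.
#' @export
plot_k_selection <- function(report) autoplot.k_selection(report)

#' Heatmap of the co-occurrence matrix
#'
#' @param cooc A `cooccurrence` from [cooccurrence_matrix()].
#' @return A ggplot tile heatmap of Spearman rho.
#' @export
plot_cooccurrence <- function(cooc) {
  m <- cooc$matrix
  df <- tibble::as_tibble(m, rownames = "taxon_a")
  long <- tidyr::pivot_longer(df, -"taxon_a", names_to = "taxon_b",
                              values_to = "rho")
  long$taxon_a <- factor(long$taxon_a, levels = rownames(m))
  long$taxon_b <- factor(long$taxon_b, levels = colnames(m))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$taxon_a, y = .data$taxon_b,
                                     fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman\nrho") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Lollipop chart of the butyrate association ranking
#'
#' @param object A `butyrate_ranking`.
#' @param ... Unused.
#' @return A ggplot object showing rho vs butyrate per candidate taxon.
#' @export
autoplot.butyrate_ranking <- function(object, ...) {
  df <- object$ranking
  df$taxon <- factor(df$taxon, levels = rev(df$taxon))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho_butyrate, y = .data$taxon)) +
    ggplot2::geom_segment(ggplot2::aes(x = 0, xend = .data$rho_butyrate,
                                       yend = .data$taxon), color = "grey60") +
    ggplot2::geom_point(size = 3, color = "#b2182b") +
    ggplot2::labs(x = "Spearman rho with fecal butyrate", y = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.butyrate_ranking
#' @param ranking A `butyrate_ranking`.
#' @export
plot_association_ranking <- function(ranking) autoplot.butyrate_ranking(ranking)
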