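# broom-style accessors for the fitted objects

#' Tidy an enterotype PAM fit
#'
#' @param x An `enterotype_fit` from [pam()].
#' @param ... Unused.
#' @return One row per sample: `sample_id`, `enterotype`, `is_medoid`.
#' @export
tidy.enterotype_fit <- function(x, ...) {
  dplyr::mutate(x$labels, is_medoid = .data$sample_id %in% x$medoid_ids)
}

#' @rdname tidy.enterotype_fit
#' @return `glance()`: one row with `k`, `n_samples`, `total_cost` and the
#'   cluster sizes.
#' @export
glance.enterotype_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    n_samples = nrow(x$labels),
    total_cost = x$total_cost,
    largest_cluster = max(x$cluster_sizes),
    smallest_cluster = min(x$cluster_sizes)
  )
}

#' Tidy a k-selection report
#'
#' @param x A `k_selection` from [choose_k()].
#' @param ... Unused.
#' @return One row per candidate k with silhouette, mean prediction
#'   strength and threshold status.
#' @export
tidy.k_selection <- function(x, ...) x$summary

#' @rdname tidy.k_selection
#' @export
glance.k_selection <- function(x, ...) {
  tibble::tibble(
    chosen_k = x$chosen_k,
    ps_threshold = x$ps_threshold,
    threshold_met = x$threshold_met,
    n_repeats = x$n_repeats
  )
}

#' Tidy a PCoA ordination
#'
#' @param x An `enterotype_pcoa` from [pcoa()].
#' @param ... Unused.
#' @return Per-sample coordinates (`sample_id`, `Axis1`, ...).
#' @export
tidy.enterotype_pcoa <- function(x, ...) x$coordinates

#' @rdname tidy.enterotype_pcoa
#' @export
glance.enterotype_pcoa <- function(x, ...) {
  tibble::tibble(
    n_axes = length(x$eigenvalues),
    prop_axis1 = x$proportion_explained[1],
    prop_axis2 = if (length(x$proportion_explained) >= 2) x$proportion_explained[2] else NA_real_,
    n_negative_eigenvalues = length(x$negative_eigenvalues)
  )
}

#' Tidy a butyrate association ranking
#'
#' @param x A `butyrate_ranking` from [phenotype_association_ranking()].
#' @param ... Unused.
#' @return The per-taxon ranking tibble, strongest butyrate correlation
#'   first.
#' @export
tidy.butyrate_ranking <- function(x, ...) x$ranking

#' @rdname tidy.butyrate_ranking
#' @return `glance()`: one row with the two gene-vs-butyrate rank
#'   correlations and sample count.
#' @export
glance.butyrate_ranking <- function(x, ...) {
  tibble::tibble(
    rho_butyrate_buk = x$gene_correlations$rho[x$gene_correlations$gene == "Buk"],
    rho_butyrate_but = x$gene_correlations$rho[x$gene_correlations$gene == "But"],
    n_samples = x$n_samples,
    n_taxa_ranked = nrow(x$ranking),
    n_skipped = length(x$skipped)
  )
}

#' Tidy a co-occurrence result
#'
#' @param x A `cooccurrence` from [cooccurrence_matrix()].
#' @param ... Unused.
#' @return Long tibble of taxon pairs with rho, p and q.
#' @export
tidy.cooccurrence <- function(x, ...) x$pairs
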