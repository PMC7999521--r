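#' Mean silhouette index of a clustering
#'
#' For each sample, \eqn{s(i) = (b_i - a_i) / \max(a_i, b_i)} where
#' \eqn{a_i} is the mean distance to the sample's own cluster (excluding
#' itself) and \eqn{b_i} the smallest mean distance to any other cluster.
#' Samples in singleton clusters get \eqn{s(i) = 0} (the standard
#' convention). Returns the mean over samples, in \[-1, 1\].
#'
#' @param dist Symmetric distance matrix.
#' @param labels Cluster labels (vector or `sample_id`/`enterotype`
#'   tibble) with at least two clusters.
#' @return A single number in \[-1, 1\].
#' @export
silhouette_index <- function(dist, labels) {
  d <- check_distance_matrix(dist)
  lab <- as_label_vector(labels)
  if (length(lab) != nrow(d)) abort("labels must match the distance matrix")
  clusters <- sort(unique(lab))
  if (length(clusters) < 2) abort("silhouette undefined for a single cluster")
  sizes <- table(factor(lab, levels = clusters))
  s <- vapply(seq_along(lab), function(i) {
    own <- lab[i]
    if (sizes[[as.character(own)]] == 1) return(0)
    a <- mean(d[i, lab == own & seq_along(lab) != i])
    b <- min(vapply(clusters[clusters != own],
                    function(cl) mean(d[i, lab == cl]), numeric(1)))
    denom <- max(a, b)
    if (denom == 0) 0 else (b - a) / denom
  }, numeric(1))
  mean(s)
}

# Prediction strength of one train/test split pair, given the full distance
# matrix. Test clusters of size < 2 are excluded from the min.
ps_one_split <- function(d, k, train, test) {
  fit_train <- pam(d[train, train, drop = FALSE], k)
  fit_test <- pam(d[test, test, drop = FALSE], k)
  train_medoids <- train[fit_train$medoid_indices]
  test_assigned <- assign_to_medoids(d[test, train_medoids, drop = FALSE])
  test_labels <- fit_test$labels$enterotype
  props <- c()
  for (j in sort(unique(test_labels))) {
    members <- which(test_labels == j)
    if (length(members) < 2) next
    a <- test_assigned[members]
    pairs_total <- choose(length(members), 2)
    pairs_co <- sum(choose(table(a), 2))
    props <- c(props, pairs_co / pairs_total)
  }
  if (length(props) == 0) return(1)
  min(props)
}

ps_from_dist <- function(d, k, n_repeats) {
  n <- nrow(d)
  per_repeat <- vapply(seq_len(n_repeats), function(r) {
    idx <- sample.int(n)
    train <- sort(idx[seq_len(floor(n / 2))])
    test <- sort(idx[(floor(n / 2) + 1):n])
    ps_one_split(d, k, train, test)
  }, numeric(1))
  structure(mean(per_repeat), per_repeat = per_repeat)
}

#' Prediction strength of a k-cluster solution
#'
#' Cross-validation stability of the clustering: the cohort is split in
#' half at random, both halves are clustered independently with PAM on
#' root-JSD, test samples are classified to the nearest train medoid, and
#' the prediction strength is the minimum over test clusters of the
#' fraction of within-cluster sample pairs that the train classification
#' keeps together (test clusters of size < 2 are excluded). The value
#' returned is the mean over `n_repeats` random splits; per-repeat values
#' are attached as the `"per_repeat"` attribute. By definition the
#' prediction strength at k = 1 is exactly 1.
#'
#' @param table Abundance tibble (counts or relative).
#' @param k Number of clusters; must satisfy `k <= n/2` so both halves can
#'   be clustered.
#' @param n_repeats Number of random 50/50 splits (default 20).
#' @param seed Optional integer seed for the split randomness.
#' @inheritParams jsd
#' @return Mean prediction strength in \[0, 1\].
#' @export
prediction_strength <- function(table, k, n_repeats = 20, seed = NULL,
                                zero_replacement = 1e-9) {
  if (k == 1) return(structure(1, per_repeat = rep(1, n_repeats)))
  d <- jsd_matrix(table, zero_replacement = zero_replacement)
  if (k > nrow(d) / 2) abort("k must be at most n/2 for 50/50 prediction strength")
  if (!is.null(seed)) set.seed(seed)
  ps_from_dist(d, k, n_repeats)
}

#' Choose the number of enterotypes
#'
#' Evaluates every candidate k by (i) the silhouette index of the full
#' cohort PAM solution on root-JSD distances and (ii) the mean prediction
#' strength over repeated 50/50 splits. The chosen k is the one with the
#' highest silhouette among candidates whose prediction strength reaches
#' `ps_threshold`; if no candidate passes, the overall silhouette maximum
#' is returned with `threshold_met = FALSE` so callers can flag the cohort
#' as weakly structured.
#'
#' @param table Abundance tibble.
#' @param k_range Candidate cluster numbers (default 2:6), within
#'   \[2, n/2\].
#' @param ps_threshold Minimum acceptable mean prediction strength
#'   (default 0.8, the permissive end of the published 0.8-0.9 guidance,
#'   suited to cohorts of about a hundred samples).
#' @param n_repeats Splits per k for prediction strength.
#' @param seed Optional integer seed (one stream drives all splits).
#' @inheritParams jsd
#' @return An object of class `k_selection`: list with `summary` (tibble
#'   of k, silhouette, prediction_strength, passes_threshold), `chosen_k`,
#'   `ps_threshold`, `threshold_met`, `per_repeat` (long tibble of
#'   per-split prediction strengths) and `dist` (the cohort distance
#'   matrix, reused by downstream steps).
#' @seealso [pam()], [prediction_strength()], [silhouette_index()]
#' @export
choose_k <- function(table, k_range = 2:6, ps_threshold = 0.8,
                     n_repeats = 20, seed = NULL, zero_replacement = 1e-9) {
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) == 0) abort("empty k_range")
  d <- jsd_matrix(table, zero_replacement = zero_replacement)
  n <- nrow(d)
  if (any(k_range < 2) || any(k_range > n / 2)) {
    abort("k_range must lie within [2, n/2]")
  }
  if (!is.null(seed)) set.seed(seed)
  rows <- purrr::map(k_range, function(k) {
    fit <- pam(d, k)
    si <- silhouette_index(d, fit$labels)
    ps <- ps_from_dist(d, k, n_repeats)
    list(k = k, silhouette = si, ps = as.numeric(ps),
         per_repeat = attr(ps, "per_repeat"))
  })
  summary <- tibble::tibble(
    k = k_range,
    silhouette = vapply(rows, `[[`, numeric(1), "silhouette"),
    prediction_strength = vapply(rows, `[[`, numeric(1), "ps")
  )
  summary$passes_threshold <- summary$prediction_strength >= ps_threshold
  eligible <- if (any(summary$passes_threshold)) {
    summary[summary$passes_threshold, ]
  } else {
    summary
  }
  chosen <- eligible$k[which.max(eligible$silhouette)]
  threshold_met <- any(summary$passes_threshold)
  if (!threshold_met) {
    warn(sprintf(
      "no k reached prediction strength %.2f; choosing k = %d by silhouette alone",
      ps_threshold, chosen
    ))
  }
  per_repeat <- tidyr::unnest(
    tibble::tibble(
      k = k_range,
      repeat_id = list(seq_len(n_repeats)),
      prediction_strength = purrr::map(rows, "per_repeat")
    ),
    c("repeat_id", "prediction_strength")
  )
  structure(list(
    summary = summary,
    chosen_k = as.integer(chosen),
    ps_threshold = ps_threshold,
    threshold_met = threshold_met,
    n_repeats = n_repeats,
    per_repeat = per_repeat,
    dist = d
  ), class = "k_selection")
}

#' @export
print.k_selection <- function(x, ...) {
  cat(sprintf("Enterotype number selection (PS threshold %.2f, %d repeats)\n",
              x$ps_threshold, x$n_repeats))
  print(x$summary)
  cat(sprintf("chosen k = %d%s\n", x$chosen_k,
              if (x$threshold_met) "" else " (no k passed the PS threshold)"))
  invisible(x)
}

#' Per-sample alpha diversity
#'
#' Community richness and diversity per sample: `observed_units`, the
#' number of taxa detected (nonzero), and `shannon`, the Shannon index
#' \eqn{H = -\sum_t p_t \log p_t} over the sample's nonzero proportions.
#' Natural log by default; `base = "2"` gives bits, matching tools that
#' report log2 Shannon.
#'
#' @param table Abundance tibble (counts or relative).
#' @param base `"e"` (default) or `"2"`.
#' @return Tibble with `sample_id`, `observed_units`, `shannon`.
#' @export
alpha_diversity <- function(table, base = c("e", "2")) {
  base <- match.arg(base)
  mat <- as_abundance_matrix(table)
  if (any(rowSums(mat) <= 0)) {
    abort(paste0("all-zero sample row(s): ",
                 paste(rownames(mat)[rowSums(mat) <= 0], collapse = ", ")))
  }
  p <- mat / rowSums(mat)
  h <- -rowSums(xlogx(p))
  if (base == "2") h <- h / log(2)
  tibble::tibble(
    sample_id = rownames(mat),
    observed_units = as.integer(rowSums(mat > 0)),
    shannon = unname(h)
  )
}
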