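#' Partitioning Around Medoids on a precomputed distance matrix
#'
#' Deterministic k-medoids in the classic Kaufman-Rousseeuw form. BUILD
#' seeds the medoids greedily (first the sample minimizing total distance
#' to all others, then repeatedly the sample giving the largest cost
#' reduction); SWAP repeatedly applies the single best cost-decreasing
#' medoid/non-medoid exchange until no exchange helps. With the default
#' `restarts = 0` there is no randomness, so runs are bit-reproducible;
#' all ties break toward the lowest sample index.
#'
#' SWAP is a steepest-descent local search: on small adversarial instances
#' it can settle in a swap-stable configuration that is not the global
#' optimum (the classic implementations behave identically). For exact
#' optimization on small problems, `restarts > 0` re-runs the descent from
#' that many random medoid seedings (driven by `seed`) and keeps the best
#' solution found.
#'
#' Clusters are renumbered by decreasing size (ties: lower medoid index
#' first), so "ET1" is always the largest enterotype and labels are stable
#' across runs.
#'
#' @param dist Symmetric distance matrix with zero diagonal (e.g. from
#'   [jsd_matrix()]).
#' @param k Number of clusters, between 1 and the number of samples.
#' @param restarts Number of additional random-initialization descents
#'   (default 0: pure deterministic BUILD+SWAP).
#' @param seed Optional integer seed for the restarts.
#' @return An object of class `enterotype_fit`: a list with `k`,
#'   `medoid_ids`, `medoid_indices`, `labels` (tibble `sample_id`,
#'   `enterotype`), `total_cost` (sum of distances of samples to their
#'   medoid) and `cluster_sizes`.
#' @seealso [assign_to_medoids()], [silhouette_index()], [choose_k()]
#' @examples
#' d <- as.matrix(dist(c(0, 1, 10, 11)))
#' pam(d, 2)$medoid_indices
#' @export
pam <- function(dist, k, restarts = 0, seed = NULL) {
  d <- check_distance_matrix(dist)
  n <- nrow(d)
  k <- as.integer(k)
  if (is.na(k) || k < 1 || k > n) abort("k must be between 1 and the number of samples")

  # BUILD
  medoids <- unname(which.min(rowSums(d)))
  dmin <- d[, medoids]
  while (length(medoids) < k) {
    candidates <- setdiff(seq_len(n), medoids)
    gains <- vapply(candidates, function(c) sum(pmax(dmin - d[, c], 0)), numeric(1))
    best <- candidates[which.max(gains)]
    medoids <- c(medoids, best)
    dmin <- pmin(dmin, d[, best])
  }

  sol <- swap_descent(d, medoids, sum(dmin))
  if (restarts > 0 && k < n) {
    if (!is.null(seed)) set.seed(seed)
    for (r in seq_len(restarts)) {
      init <- sort(sample.int(n, k))
      start_cost <- sum(do.call(pmin, asplit(d[, init, drop = FALSE], 2)))
      cand <- swap_descent(d, init, start_cost)
      if (cand$cost < sol$cost - 1e-12) sol <- cand
    }
  }
  medoids <- sort(unname(sol$medoids))

  raw_labels <- unname(apply(d[, medoids, drop = FALSE], 1, which.min))
  # renumber: decreasing cluster size, ties toward the lower medoid index
  sizes <- tabulate(raw_labels, nbins = k)
  order_clusters <- order(-sizes, medoids)
  remap <- integer(k)
  remap[order_clusters] <- seq_len(k)
  labels <- remap[raw_labels]
  medoids <- medoids[order_clusters]

  structure(list(
    k = k,
    medoid_indices = medoids,
    medoid_ids = rownames(d)[medoids],
    labels = tibble::tibble(sample_id = rownames(d), enterotype = as.integer(labels)),
    total_cost = sum(d[cbind(seq_len(n), medoids[labels])]),
    cluster_sizes = as.integer(tabulate(labels, nbins = k))
  ), class = "enterotype_fit")
}

# SWAP phase: accept the single best strictly improving exchange, repeat.
# For each removed medoid, the cost of every candidate replacement is a
# column minimum against the fallback distances, so each pass is a handful
# of vectorized matrix operations.
swap_descent <- function(d, medoids, current) {
  n <- nrow(d)
  k <- length(medoids)
  if (k >= n) return(list(medoids = medoids, cost = current))
  repeat {
    others <- which(!(seq_len(n) %in% medoids))
    dm <- d[, medoids, drop = FALSE]
    nearest <- max.col(-dm, ties.method = "first")
    dnearest <- dm[cbind(seq_len(n), nearest)]
    dm2 <- dm
    dm2[cbind(seq_len(n), nearest)] <- Inf
    dsecond <- if (k > 1) do.call(pmin, asplit(dm2, 2)) else rep(Inf, n)
    best_delta <- -1e-12
    best_swap <- NULL
    for (mi in seq_along(medoids)) {
      base <- ifelse(nearest == mi, dsecond, dnearest)
      trial_costs <- colSums(pmin(d[, others, drop = FALSE], base))
      h_best <- which.min(trial_costs)
      delta <- trial_costs[h_best] - current
      if (delta < best_delta) {
        best_delta <- delta
        best_swap <- c(mi, others[h_best])
      }
    }
    if (is.null(best_swap)) break
    medoids[best_swap[1]] <- best_swap[2]
    current <- current + best_delta
  }
  list(medoids = medoids, cost = current)
}

#' @export
print.enterotype_fit <- function(x, ...) {
  cat(sprintf(
    "PAM enterotype fit: k = %d, n = %d, total cost = %.4f\n",
    x$k, nrow(x$labels), x$total_cost
  ))
  cat("cluster sizes:", paste(x$cluster_sizes, collapse = ", "), "\n")
  cat("medoids:", paste(x$medoid_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Classify samples to the nearest medoid
#'
#' Nearest-medoid classification used by prediction strength to carry a
#' train-half clustering onto held-out samples. Ties go to the
#' lowest-index medoid (the first column).
#'
#' @param dist_to_medoids Matrix of distances, one row per sample to
#'   classify and one column per medoid (columns in cluster order 1..k).
#' @return Integer vector of cluster assignments in 1..k, named by the
#'   rownames of `dist_to_medoids` when present.
#' @export
assign_to_medoids <- function(dist_to_medoids) {
  m <- as.matrix(dist_to_medoids)
  if (ncol(m) == 0) abort("empty medoid set")
  if (anyNA(m) || any(!is.finite(m))) abort("distances to medoids must be finite")
  res <- as.integer(apply(m, 1, which.min))
  names(res) <- rownames(m)
  res
}
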