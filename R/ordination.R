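#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: the squared distances are double-centered
#' (Gower), \eqn{B = -\tfrac12 C D^{(2)} C} with \eqn{C = I - 11'/n}, and
#' eigendecomposed; coordinates are eigenvectors scaled by the square root
#' of their eigenvalue, so Euclidean distances among coordinates reproduce
#' any Euclidean-embeddable input exactly. Root-JSD is a metric but not
#' always Euclidean-embeddable, so small negative eigenvalues can occur;
#' they are dropped (no Lingoes/Cailliez correction, matching common
#' ecology-package defaults) and recorded in `negative_eigenvalues`.
#' `proportion_explained` is relative to the sum of positive eigenvalues.
#'
#' Each axis has an arbitrary sign; it is fixed by making the
#' largest-magnitude coordinate on the axis positive, so results are
#' bit-stable.
#'
#' @param dist Symmetric distance matrix with zero diagonal.
#' @param n_axes Number of axes to retain (default: all positive ones).
#' @return Object of class `enterotype_pcoa`: list with `coordinates`
#'   (tibble `sample_id`, `Axis1`, ...), `eigenvalues` (retained, positive,
#'   descending), `proportion_explained`, and `negative_eigenvalues`.
#' @examples
#' d <- as.matrix(dist(c(0, 1, 3)))
#' pcoa(d)$eigenvalues
#' @export
pcoa <- function(dist, n_axes = NULL) {
  d <- check_distance_matrix(dist)
  n <- nrow(d)
  a <- -0.5 * d^2
  centered <- a - outer(rowMeans(a), rep(1, n)) -
    outer(rep(1, n), colMeans(a)) + mean(a)
  eig <- eigen((centered + t(centered)) / 2, symmetric = TRUE)
  tol <- max(abs(eig$values)) * 1e-8
  pos <- which(eig$values > tol)
  if (length(pos) == 0) abort("no positive eigenvalues: degenerate distance matrix")
  values <- eig$values[pos]
  vectors <- eig$vectors[, pos, drop = FALSE]
  coords <- vectors %*% diag(sqrt(values), nrow = length(values))
  # sign convention: largest-magnitude loading on each axis is positive
  for (j in seq_len(ncol(coords))) {
    i_max <- which.max(abs(coords[, j]))
    if (coords[i_max, j] < 0) coords[, j] <- -coords[, j]
  }
  if (!is.null(n_axes)) {
    keep <- seq_len(min(n_axes, ncol(coords)))
    coords <- coords[, keep, drop = FALSE]
    values_kept <- values[keep]
  } else {
    values_kept <- values
  }
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(
    coordinates = tibble::as_tibble(cbind(
      tibble::tibble(sample_id = rownames(d)),
      tibble::as_tibble(coords)
    )),
    eigenvalues = values_kept,
    proportion_explained = values_kept / sum(values),
    negative_eigenvalues = eig$values[eig$values < -tol]
  ), class = "enterotype_pcoa")
}

#' @export
print.enterotype_pcoa <- function(x, ...) {
  cat(sprintf("PCoA: %d samples, %d retained axes\n",
              nrow(x$coordinates), length(x$eigenvalues)))
  cat("proportion explained:",
      paste(sprintf("%.3f", head(x$proportion_explained, 5)), collapse = ", "),
      if (length(x$proportion_explained) > 5) "..." else "", "\n")
  if (length(x$negative_eigenvalues) > 0) {
    cat(sprintf("dropped %d negative eigenvalue(s), largest magnitude %.3g\n",
                length(x$negative_eigenvalues),
                max(abs(x$negative_eigenvalues))))
  }
  invisible(x)
}
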