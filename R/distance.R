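#' Root Jensen-Shannon divergence between two probability vectors
#'
#' The distance used for enterotype clustering:
#' \deqn{D(p, q) = \sqrt{\tfrac12 KL(p \| m) + \tfrac12 KL(q \| m)}, \quad
#'   m = (p + q)/2,}
#' with Kullback-Leibler divergences in natural log, so
#' \eqn{D \in [0, \sqrt{\ln 2}]} and identical profiles are at distance 0.
#' The square root of the Jensen-Shannon divergence is a true metric
#' (symmetric, zero only at identity, triangle inequality), which is what
#' k-medoids and silhouette computations assume; the plain divergence is
#' available with `root = FALSE`.
#'
#' Zero entries are replaced by `zero_replacement` and the vector is
#' re-normalized before the KL terms are evaluated, so taxa absent from one
#' profile but present in the other contribute a finite penalty. The
#' replacement is applied per vector (not per pair), so identical profiles
#' stay at distance exactly 0. With `zero_replacement = 0` the convention
#' \eqn{0 \log 0 = 0} is used and disjoint supports attain the maximum
#' \eqn{\sqrt{\ln 2}} exactly.
#'
#' @param p,q Non-negative vectors of equal length summing to 1 (within
#'   1e-6).
#' @param zero_replacement Value substituted for exact zeros before
#'   re-normalization. Default 1e-9, small enough that appending zero taxa
#'   perturbs distances by less than 1e-6.
#' @param root If `TRUE` (default) return the metric square root.
#' @return A single non-negative number.
#' @examples
#' jsd(c(0.5, 0.5), c(0.25, 0.75))
#' jsd(c(1, 0), c(0, 1), zero_replacement = 0) # sqrt(log(2))
#' @export
jsd <- function(p, q, zero_replacement = 1e-9, root = TRUE) {
  if (length(p) != length(q)) abort("p and q must have the same length")
  if (any(p < 0) || any(q < 0)) abort("probability vectors must be non-negative")
  if (sum(p) <= 0 || sum(q) <= 0) abort("cannot normalize an all-zero vector")
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    abort("p and q must each sum to 1")
  }
  p <- replace_zeros(p, zero_replacement)
  q <- replace_zeros(q, zero_replacement)
  m <- (p + q) / 2
  d2 <- 0.5 * kl_div(p, m) + 0.5 * kl_div(q, m)
  d2 <- max(d2, 0)
  if (root) sqrt(d2) else d2
}

replace_zeros <- function(p, zero_replacement) {
  if (zero_replacement > 0 && any(p == 0)) {
    p[p == 0] <- zero_replacement
    p <- p / sum(p)
  }
  p
}

kl_div <- function(p, m) {
  i <- p > 0
  sum(p[i] * log(p[i] / m[i]))
}

#' Pairwise root-JSD distance matrix of a cohort
#'
#' Computes the root Jensen-Shannon divergence between every pair of sample
#' profiles of an abundance table. Counts are converted to relative
#' abundances first. Uses the entropy identity
#' \eqn{JSD(p,q) = H(m) - (H(p) + H(q))/2} for an O(n^2) vectorized sweep.
#'
#' @param table Abundance tibble (or samples-by-taxa matrix).
#' @inheritParams jsd
#' @return A symmetric n-by-n matrix with zero diagonal and sample ids as
#'   dimnames.
#' @seealso [jsd()], [pam()], [pcoa()]
#' @export
jsd_matrix <- function(table, zero_replacement = 1e-9, root = TRUE) {
  mat <- as_abundance_matrix(table)
  if (nrow(mat) < 2) abort("need at least 2 samples for a distance matrix")
  mat <- as_abundance_matrix(normalize_relative(mat))
  p <- t(apply(mat, 1, replace_zeros, zero_replacement = zero_replacement))
  n <- nrow(p)
  h <- -rowSums(xlogx(p))
  d <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1)) {
    rest <- (i + 1):n
    m <- (p[rest, , drop = FALSE] + rep(p[i, ], each = length(rest))) / 2
    hm <- -rowSums(xlogx(m))
    d2 <- pmax(hm - (h[i] + h[rest]) / 2, 0)
    d[i, rest] <- d[rest, i] <- if (root) sqrt(d2) else d2
  }
  d
}

xlogx <- function(x) {
  out <- x * log(x)
  out[x == 0] <- 0
  out
}

#' Read and write square distance matrices as TSV
#'
#' Square tab-delimited layout with sample ids in the first column and in
#' the header, so a clustering-only run can start from a precomputed
#' distance matrix.
#'
#' @param d Distance matrix with dimnames.
#' @param path File path.
#' @return `read_distance_tsv()` returns a validated symmetric matrix.
#' @export
write_distance_tsv <- function(d, path) {
  d <- check_distance_matrix(d)
  tb <- tibble::as_tibble(d, rownames = "sample_id")
  readr::write_tsv(tb, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  mat <- as.matrix(tb[-1])
  rownames(mat) <- as.character(tb[[1]])
  check_distance_matrix(mat)
}
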