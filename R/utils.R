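# internal helpers shared across modules

# Coerce a samples-by-taxa tibble (first column = sample ids) to a numeric
# matrix with sample ids as rownames. Validates ids and values.
as_abundance_matrix <- function(table) {
  if (is.matrix(table)) {
    if (is.null(rownames(table))) rownames(table) <- paste0("S", seq_len(nrow(table)))
    if (is.null(colnames(table))) colnames(table) <- paste0("T", seq_len(ncol(table)))
    storage.mode(table) <- "double"
    check_abundance_values(table)
    return(table)
  }
  stopifnot(is.data.frame(table))
  if (ncol(table) < 2) abort("abundance table needs a sample-id column plus at least one taxon column")
  ids <- as.character(table[[1]])
  if (anyDuplicated(ids)) abort("duplicate sample ids in abundance table")
  body <- table[-1]
  not_num <- names(body)[!vapply(body, is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(paste0("non-numeric abundance column(s): ", paste(not_num, collapse = ", ")))
  }
  if (anyDuplicated(names(body))) abort("duplicate taxon ids in abundance table")
  mat <- as.matrix(body)
  rownames(mat) <- ids
  check_abundance_values(mat)
  mat
}

check_abundance_values <- function(mat) {
  if (anyNA(mat)) abort("missing abundance values (ragged or NA cells)")
  if (any(mat < 0)) abort("negative abundance")
  invisible(mat)
}

as_abundance_tibble <- function(mat) {
  tibble::as_tibble(mat, rownames = "sample_id")
}

# Unit detection: counts when every value is integral, relative when every
# row sums to ~1. Anything else is ambiguous and rejected where a unit is
# required.
detect_unit <- function(mat, tol = 1e-6) {
  if (all(abs(mat - round(mat)) < 1e-9)) return("counts")
  if (all(abs(rowSums(mat) - 1) < tol)) return("relative")
  "unknown"
}

is_relative <- function(mat, tol = 1e-6) {
  all(abs(rowSums(mat) - 1) < tol)
}

# Validate a square symmetric distance matrix; returns it with ids.
check_distance_matrix <- function(d, tol = 1e-8) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) abort("distance matrix must be square")
  if (anyNA(d)) abort("distance matrix contains missing values")
  if (max(abs(d - t(d))) > tol) abort("distance matrix is not symmetric")
  if (any(abs(diag(d)) > tol)) abort("distance matrix diagonal must be zero")
  if (any(d < -tol)) abort("distance matrix has negative entries")
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  d
}

# Extract an integer label vector (named by sample id when available) from
# either a labels tibble (sample_id, enterotype) or a plain vector.
as_label_vector <- function(labels) {
  if (is.data.frame(labels)) {
    stopifnot(ncol(labels) >= 2)
    out <- as.integer(labels[[2]])
    names(out) <- as.character(labels[[1]])
    return(out)
  }
  out <- as.integer(labels)
  names(out) <- names(labels)
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples,
#' used to score recovery of planted enterotypes. 1 means identical
#' partitions up to relabeling; 0 is the expectation under independent
#' random partitions.
#'
#' @param a,b Label vectors (or two-column `sample_id`/label tibbles) of
#'   equal length.
#' @return A single number in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))
#' @export
adjusted_rand_index <- function(a, b) {
  a <- as_label_vector(a)
  b <- as_label_vector(b)
  if (length(a) != length(b)) abort("partitions must have equal length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}
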