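#' Read a samples-by-taxa abundance table
#'
#' Reads a genus-level (or any-rank) abundance table from wide TSV or dense
#' BIOM-JSON (v1.0) into a tibble whose first column, `sample_id`, holds the
#' sample identifiers and whose remaining columns are taxa. The unit of the
#' table is auto-detected: all-integral values are treated as sequencing
#' counts, rows summing to one as relative abundances; anything else is
#' rejected as ambiguous.
#'
#' TSV dialect: tab-delimited, lines starting with `#` are comments, the
#' first column holds row ids. BIOM tables follow the BIOM convention of
#' taxa (observations) in rows, so `orientation = "taxa_rows"` is their
#' default.
#'
#' @param path Path to the input file.
#' @param format `"tsv_wide"` or `"biom_json"` (dense BIOM v1.0; requires
#'   the biomformat package).
#' @param orientation `"samples_rows"` (default for TSV) or `"taxa_rows"`;
#'   the table is transposed on read so samples always end up in rows.
#' @return A tibble with a `sample_id` column and one numeric column per
#'   taxon. The detected unit (`"counts"` or `"relative"`) is stored in the
#'   `"unit"` attribute.
#' @seealso [normalize_relative()], [filter_low_abundance()],
#'   [write_abundance_table()]
#' @export
read_abundance_table <- function(path,
                                 format = c("tsv_wide", "biom_json"),
                                 orientation = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  if (format == "tsv_wide") {
    orientation <- orientation %||% "samples_rows"
    raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                           progress = FALSE, name_repair = "minimal")
    if (anyDuplicated(names(raw)[-1])) abort("duplicate column ids in abundance table")
    mat <- as_abundance_matrix(raw)
  } else {
    orientation <- orientation %||% "taxa_rows"
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("reading BIOM files requires the biomformat package")
    }
    b <- biomformat::read_biom(path)
    mat <- as(biomformat::biom_data(b), "matrix")
    storage.mode(mat) <- "double"
    check_abundance_values(mat)
  }
  orientation <- match.arg(orientation, c("samples_rows", "taxa_rows"))
  if (orientation == "taxa_rows") mat <- t(mat)
  if (anyDuplicated(rownames(mat))) abort("duplicate sample ids in abundance table")
  if (anyDuplicated(colnames(mat))) abort("duplicate taxon ids in abundance table")
  unit <- detect_unit(mat)
  if (unit == "unknown") {
    abort("cannot determine unit: values are neither all integral (counts) nor row-normalized (relative)")
  }
  out <- as_abundance_tibble(mat)
  attr(out, "unit") <- unit
  out
}

#' Write an abundance table
#'
#' Writes a samples-by-taxa tibble as wide TSV (samples in rows) or dense
#' BIOM-JSON v1.0 (taxa in rows, per the BIOM convention).
#'
#' @param table Abundance tibble (first column sample ids).
#' @param path Output path.
#' @param format `"tsv_wide"` or `"biom_json"`.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(table, path, format = c("tsv_wide", "biom_json")) {
  format <- match.arg(format)
  mat <- as_abundance_matrix(table)
  if (format == "tsv_wide") {
    readr::write_tsv(as_abundance_tibble(mat), path, progress = FALSE)
  } else {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("writing BIOM files requires the biomformat package")
    }
    biomformat::write_biom(biomformat::make_biom(t(mat)), path)
  }
  invisible(path)
}

#' Convert abundances to relative (per-sample proportions)
#'
#' Divides each sample row by its total so rows sum to one. Idempotent and
#' scale-invariant within rows; proportions among taxa are preserved.
#'
#' @param table Abundance tibble (counts or relative).
#' @return A tibble of the same shape with rows summing to 1.
#' @examples
#' tb <- tibble::tibble(sample_id = c("a", "b"), x = c(2, 1), y = c(2, 3))
#' normalize_relative(tb)
#' @export
normalize_relative <- function(table) {
  mat <- as_abundance_matrix(table)
  totals <- rowSums(mat)
  if (any(totals <= 0)) {
    bad <- rownames(mat)[totals <= 0]
    abort(paste0("all-zero sample row(s): ", paste(bad, collapse = ", ")))
  }
  out <- as_abundance_tibble(mat / totals)
  attr(out, "unit") <- "relative"
  out
}

#' Drop ultra-rare taxa before enterotyping
#'
#' Optional noise filter. A taxon is kept when its mean relative abundance
#' reaches `min_mean_rel`, or when its prevalence (fraction of samples in
#' which it is detected) reaches `min_prevalence`; a threshold of 0
#' deactivates that rule. The defaults (0, 0) keep every taxon, i.e. no
#' filtering — the behaviour used throughout the shipped pipeline — because
#' classical enterotyping clusters on the full genus profile; the filter is
#' offered because the original enterotype methodology literature commonly
#' removes ultra-rare genera before clustering.
#'
#' Rows of the returned table are re-normalized to sum to one. The removed
#' taxa are recorded in the `"removed_taxa"` attribute.
#'
#' @param table Abundance tibble; normalized internally if given as counts.
#' @param min_mean_rel Minimum mean relative abundance (0 disables).
#' @param min_prevalence Minimum detection fraction across samples
#'   (0 disables).
#' @return Filtered, re-normalized tibble with attribute `removed_taxa`.
#' @export
filter_low_abundance <- function(table, min_mean_rel = 0, min_prevalence = 0) {
  table <- normalize_relative(table)
  mat <- as_abundance_matrix(table)
  mean_rel <- colMeans(mat)
  prevalence <- colMeans(mat > 0)
  keep <- rep(min_mean_rel <= 0 && min_prevalence <= 0, ncol(mat))
  if (min_mean_rel > 0) keep <- keep | mean_rel >= min_mean_rel
  if (min_prevalence > 0) keep <- keep | prevalence >= min_prevalence
  if (!any(keep)) abort("low-abundance filter removed all taxa")
  removed <- colnames(mat)[!keep]
  out <- normalize_relative(as_abundance_tibble(mat[, keep, drop = FALSE]))
  attr(out, "removed_taxa") <- removed
  out
}

#' Read a per-sample phenotype table
#'
#' Reads a TSV with one row per sample: fecal butyrate content
#' (`butyrate_mg_per_g`, mg per g fresh feces), terminal butyrate-synthesis
#' gene copies (`buk_log10_copies`, `but_log10_copies`, log10 copies per g
#' feces) and any additional numeric covariate columns (water %, pH,
#' organic matter, ...). The first column is taken as `sample_id`.
#'
#' @param path Path to the TSV.
#' @return A tibble with `sample_id` plus numeric phenotype columns.
#' @export
read_phenotype_table <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  names(tb)[1] <- "sample_id"
  tb$sample_id <- as.character(tb$sample_id)
  if (anyDuplicated(tb$sample_id)) abort("duplicate sample ids in phenotype table")
  not_num <- names(tb)[-1][!vapply(tb[-1], is.numeric, logical(1))]
  if (length(not_num) > 0) {
    abort(paste0("non-numeric phenotype column(s): ", paste(not_num, collapse = ", ")))
  }
  tb
}

#' Align an abundance table with a phenotype table
#'
#' Inner-joins the two tables on sample id and reports what was dropped on
#' either side, because cohorts frequently have samples with sequencing
#' data but no phenotype measurement (or vice versa).
#'
#' @param abundance Abundance tibble (first column sample ids).
#' @param phenotype Phenotype tibble (first column sample ids).
#' @return A list with elements `abundance`, `phenotype` (both restricted
#'   to the shared samples, in the abundance table's order),
#'   `dropped_abundance` and `dropped_phenotype` (character vectors of ids).
#' @export
align_tables <- function(abundance, phenotype) {
  ab_ids <- as.character(abundance[[1]])
  ph_ids <- as.character(phenotype[[1]])
  common <- ab_ids[ab_ids %in% ph_ids]
  dropped_ab <- setdiff(ab_ids, common)
  dropped_ph <- setdiff(ph_ids, common)
  if (length(dropped_ab) > 0 || length(dropped_ph) > 0) {
    inform(sprintf(
      "align_tables: dropped %d abundance-only and %d phenotype-only sample(s)",
      length(dropped_ab), length(dropped_ph)
    ))
  }
  if (length(common) == 0) abort("no samples shared between abundance and phenotype tables")
  list(
    abundance = abundance[match(common, ab_ids), , drop = FALSE],
    phenotype = phenotype[match(common, ph_ids), , drop = FALSE],
    dropped_abundance = dropped_ab,
    dropped_phenotype = dropped_ph
  )
}

#' Read or write enterotype label files
#'
#' Labels are stored as two-column TSV (`sample_id`, `enterotype`).
#'
#' @param path Path to the TSV.
#' @return `read_labels()` returns a tibble with `sample_id` and integer
#'   `enterotype`.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) abort(paste0("input file not found: ", path))
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE)
  names(tb)[1:2] <- c("sample_id", "enterotype")
  tb$sample_id <- as.character(tb$sample_id)
  tb$enterotype <- as.integer(tb$enterotype)
  if (anyNA(tb$enterotype)) abort("non-integer enterotype labels")
  tb[1:2]
}

#' @rdname read_labels
#' @param labels Labels tibble.
#' @export
write_labels <- function(labels, path) {
  readr::write_tsv(labels, path, progress = FALSE)
  invisible(path)
}
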