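# Pipeline orchestration: each run_* function executes a stage of the
# analysis, writes its artifacts as TSV plus a JSON run manifest, and
# returns the in-memory results. Output directories are staged and renamed
# into place so a failed run never leaves partial results.

pkg_version <- function() as.character(utils::packageVersion("enterotyper"))

write_manifest <- function(dir, stage, params, inputs = character()) {
  digests <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs[file.exists(inputs)]))
  } else {
    list()
  }
  manifest <- list(
    tool = "enterotyper",
    version = pkg_version(),
    stage = stage,
    parameters = params,
    input_digests = digests,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

# Run fn(staging_dir) and atomically rename the staging dir to out_dir.
with_staged_dir <- function(out_dir, overwrite, fn) {
  if (dir.exists(out_dir) && !overwrite) {
    abort(paste0("output directory exists: ", out_dir, " (set overwrite = TRUE)"))
  }
  staging <- paste0(out_dir, ".staging-", Sys.getpid())
  dir.create(staging, recursive = TRUE, showWarnings = FALSE)
  on.exit(unlink(staging, recursive = TRUE), add = TRUE)
  result <- fn(staging)
  if (dir.exists(out_dir)) unlink(out_dir, recursive = TRUE)
  if (!file.rename(staging, out_dir)) {
    # cross-device fallback
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.copy(list.files(staging, full.names = TRUE), out_dir, recursive = TRUE)
  }
  result
}

resolve_abundance <- function(x) {
  if (is.character(x)) read_abundance_table(x) else x
}

#' Run the enterotype-discovery stage
#'
#' Executes normalize (optional low-abundance filter) -> root-JSD distance
#' matrix -> k selection by prediction strength and silhouette -> PAM at
#' the chosen k -> PCoA, and writes `ksel.tsv`, `labels.tsv`, `pcoa.tsv`,
#' `distance.tsv` and `manifest.json` into `out_dir`.
#'
#' @param abundance Abundance tibble or path to a wide TSV.
#' @param out_dir Output directory (created; staged atomically).
#' @param k_range,ps_threshold,n_repeats,seed Passed to [choose_k()].
#' @param min_mean_rel,min_prevalence Passed to [filter_low_abundance()];
#'   the defaults (0, 0) apply no filter.
#' @param zero_replacement Passed to [jsd_matrix()].
#' @param overwrite Replace an existing `out_dir`.
#' @return A list with `labels`, `fit` ([pam()] result), `k_selection`,
#'   `ordination` and `dist`, invisibly writable artifacts already on disk.
#' @export
run_enterotype <- function(abundance, out_dir, k_range = 2:6,
                           ps_threshold = 0.8, n_repeats = 20, seed = NULL,
                           min_mean_rel = 0, min_prevalence = 0,
                           zero_replacement = 1e-9, overwrite = FALSE) {
  input_path <- if (is.character(abundance)) abundance else character()
  table <- resolve_abundance(abundance)
  table <- normalize_relative(table)
  if (min_mean_rel > 0 || min_prevalence > 0) {
    table <- filter_low_abundance(table, min_mean_rel, min_prevalence)
  }
  ks <- choose_k(table, k_range = k_range, ps_threshold = ps_threshold,
                 n_repeats = n_repeats, seed = seed,
                 zero_replacement = zero_replacement)
  fit <- pam(ks$dist, ks$chosen_k)
  ord <- pcoa(ks$dist)
  with_staged_dir(out_dir, overwrite, function(dir) {
    readr::write_tsv(ks$summary, file.path(dir, "ksel.tsv"), progress = FALSE)
    write_labels(fit$labels, file.path(dir, "labels.tsv"))
    readr::write_tsv(ord$coordinates, file.path(dir, "pcoa.tsv"), progress = FALSE)
    write_distance_tsv(ks$dist, file.path(dir, "distance.tsv"))
    write_manifest(dir, "enterotype", list(
      k_range = k_range, ps_threshold = ps_threshold, n_repeats = n_repeats,
      seed = seed, min_mean_rel = min_mean_rel, min_prevalence = min_prevalence,
      zero_replacement = zero_replacement, log_base = "e",
      chosen_k = ks$chosen_k, threshold_met = ks$threshold_met,
      medoids = fit$medoid_ids, total_cost = fit$total_cost,
      eigenvalues = ord$eigenvalues
    ), inputs = input_path)
  })
  invisible(list(labels = fit$labels, fit = fit, k_selection = ks,
                 ordination = ord, dist = ks$dist))
}

#' Run the association stage
#'
#' Produces the statistics layer for a labeled cohort: per-taxon,
#' alpha-diversity and phenotype Kruskal-Wallis tables with compact
#' letters (`group_tests_taxa.tsv`, `group_tests_alpha.tsv`,
#' `group_tests_phenotype.tsv`), the Spearman co-occurrence matrix of the
#' predominant genera (`cooccurrence.tsv` square, `cooccurrence_pairs.tsv`
#' long with p and q) and the butyrate producer ranking
#' (`butyrate_ranking.tsv`, `gene_correlations.tsv`).
#'
#' @param abundance Abundance tibble or TSV path.
#' @param phenotype Phenotype tibble or TSV path.
#' @param labels Labels tibble or TSV path (`sample_id`, `enterotype`).
#' @param candidate_taxa Taxa to rank against butyrate (default: the nine
#'   candidate butyrate-producer genera of the shipped roster).
#' @param out_dir Output directory.
#' @param alpha Significance level for letter displays.
#' @param top_n Number of predominant genera in the co-occurrence matrix.
#' @param overwrite Replace an existing `out_dir`.
#' @return A list with `taxa_tests`, `alpha_tests`, `phenotype_tests`,
#'   `cooccurrence`, `ranking`, invisibly.
#' @export
run_association <- function(abundance, phenotype, labels,
                            candidate_taxa = producer_genera,
                            out_dir, alpha = 0.05, top_n = 12,
                            overwrite = FALSE) {
  input_paths <- c(
    if (is.character(abundance)) abundance,
    if (is.character(phenotype)) phenotype,
    if (is.character(labels)) labels
  )
  table <- resolve_abundance(abundance)
  if (is.character(phenotype)) phenotype <- read_phenotype_table(phenotype)
  if (is.character(labels)) labels <- read_labels(labels)
  aligned <- align_tables(table, phenotype)
  if (nrow(aligned$abundance) < 10) {
    abort("fewer than 10 samples shared between abundance and phenotype tables")
  }
  table <- aligned$abundance
  phenotype <- aligned$phenotype
  lab <- labels[labels$sample_id %in% table[[1]], ]
  rel <- normalize_relative(table)

  taxa_tests <- per_feature_group_tests(rel, lab, alpha = alpha)
  alpha_div <- alpha_diversity(table)
  alpha_tests <- per_feature_group_tests(alpha_div, lab, alpha = alpha)
  phenotype_tests <- per_feature_group_tests(phenotype, lab, alpha = alpha)
  cooc <- cooccurrence_matrix(rel, top_n = top_n)
  ranking <- phenotype_association_ranking(table, phenotype, candidate_taxa)

  with_staged_dir(out_dir, overwrite, function(dir) {
    readr::write_tsv(taxa_tests, file.path(dir, "group_tests_taxa.tsv"), progress = FALSE)
    readr::write_tsv(alpha_tests, file.path(dir, "group_tests_alpha.tsv"), progress = FALSE)
    readr::write_tsv(phenotype_tests, file.path(dir, "group_tests_phenotype.tsv"), progress = FALSE)
    readr::write_tsv(tibble::as_tibble(cooc$matrix, rownames = "taxon"),
                     file.path(dir, "cooccurrence.tsv"), progress = FALSE)
    readr::write_tsv(cooc$pairs, file.path(dir, "cooccurrence_pairs.tsv"), progress = FALSE)
    readr::write_tsv(ranking$ranking, file.path(dir, "butyrate_ranking.tsv"), progress = FALSE)
    readr::write_tsv(ranking$gene_correlations,
                     file.path(dir, "gene_correlations.tsv"), progress = FALSE)
    write_manifest(dir, "association", list(
      alpha = alpha, top_n = top_n, candidate_taxa = candidate_taxa,
      skipped_candidates = ranking$skipped,
      dropped_abundance = aligned$dropped_abundance,
      dropped_phenotype = aligned$dropped_phenotype
    ), inputs = input_paths)
  })
  invisible(list(taxa_tests = taxa_tests, alpha_tests = alpha_tests,
                 phenotype_tests = phenotype_tests, cooccurrence = cooc,
                 ranking = ranking))
}

#' Simulate a cohort to disk
#'
#' Generates a synthetic cohort with [generate_cohort()] and writes
#' `abundance.tsv`, `phenotype.tsv`, `truth_labels.tsv` and
#' `manifest.json` (which embeds the phenotype coefficients and couplings)
#' into `out_dir`.
#'
#' @param config A `cohort_config`, or a path to a YAML/JSON file with
#'   fields overriding [default_config()] (scalar fields only: n_samples,
#'   k, concentration, seed, butyrate_noise_sd, but_target_rho,
#'   buk_target_rho).
#' @param out_dir Output directory.
#' @param overwrite Replace an existing `out_dir`.
#' @return The generated cohort list, invisibly.
#' @export
run_simulate <- function(config = default_config(), out_dir, overwrite = FALSE) {
  if (is.character(config)) config <- load_config(config)
  validate_config(config)
  cohort <- generate_cohort(config)
  with_staged_dir(out_dir, overwrite, function(dir) {
    write_abundance_table(cohort$abundance, file.path(dir, "abundance.tsv"))
    readr::write_tsv(cohort$phenotype, file.path(dir, "phenotype.tsv"), progress = FALSE)
    readr::write_tsv(cohort$truth$component_labels,
                     file.path(dir, "truth_labels.tsv"), progress = FALSE)
    write_manifest(dir, "simulate", list(
      n_samples = config$n_samples, k = config$k,
      concentration = config$concentration, seed = config$seed,
      depth_range = config$depth_range,
      phenotype_coefficients = cohort$truth$phenotype_coefficients,
      gene_copy_couplings = as.list(cohort$truth$gene_copy_couplings)
    ))
  })
  invisible(cohort)
}

# Load a config file (YAML or JSON) of scalar overrides onto the defaults.
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("config file not found: ", path))
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  allowed <- c("n_samples", "k", "concentration", "seed",
               "butyrate_noise_sd", "but_target_rho", "buk_target_rho")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")))
  }
  base_args <- raw[intersect(names(raw), c("n_samples", "k", "concentration", "seed"))]
  config <- do.call(default_config, base_args)
  for (f in setdiff(names(raw), names(base_args))) config[[f]] <- raw[[f]]
  validate_config(config)
  config
}

#' Run the full pipeline on a synthetic cohort
#'
#' Convenience wrapper: simulate -> enterotype -> associate, writing each
#' stage into a subdirectory of `out_dir`.
#'
#' @inheritParams run_simulate
#' @inheritParams run_enterotype
#' @return A list with the three stage results, invisibly.
#' @export
run_all <- function(config = default_config(), out_dir, k_range = 2:6,
                    ps_threshold = 0.8, n_repeats = 20, overwrite = FALSE) {
  if (is.character(config)) config <- load_config(config)
  cohort <- run_simulate(config, file.path(out_dir, "simulate"), overwrite = overwrite)
  ent <- run_enterotype(cohort$abundance, file.path(out_dir, "enterotype"),
                        k_range = k_range, ps_threshold = ps_threshold,
                        n_repeats = n_repeats, seed = config$seed,
                        overwrite = overwrite)
  assoc <- run_association(cohort$abundance, cohort$phenotype, ent$labels,
                           out_dir = file.path(out_dir, "associate"),
                           overwrite = overwrite)
  invisible(list(simulate = cohort, enterotype = ent, associate = assoc))
}
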