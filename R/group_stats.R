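#' Kruskal-Wallis rank test
#'
#' Nonparametric comparison of a feature among enterotype groups, via
#' [stats::kruskal.test()] (mid-rank ties, the standard tie-correction
#' divisor, chi-square p-value with k - 1 degrees of freedom). The one
#' edge case handled specially: when every value is identical the tie
#' correction degenerates and the test statistic is defined as 0 with
#' p = 1.
#'
#' @param values Numeric vector of observations.
#' @param groups Group labels, same length as `values`; at least two
#'   groups, each with at least one observation.
#' @return Tibble with `statistic` (H), `df`, `p.value`.
#' @examples
#' kruskal_wallis(1:9, rep(1:3, each = 3)) # H = 7.2
#' @export
kruskal_wallis <- function(values, groups) {
  if (length(values) != length(groups)) abort("values and groups must have equal length")
  g <- factor(groups)
  if (nlevels(g) < 2) abort("need at least two groups")
  if (length(unique(values)) == 1) {
    return(tibble::tibble(statistic = 0, df = nlevels(g) - 1L, p.value = 1))
  }
  fit <- kruskal.test(values, g)
  tibble::tibble(
    statistic = unname(fit$statistic),
    df = as.integer(unname(fit$parameter)),
    p.value = unname(fit$p.value)
  )
}

#' Spearman rank correlation
#'
#' Tie-safe Spearman rho (Pearson correlation of mid-ranks, via
#' [stats::cor()]) with a p-value from the t-approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom,
#' the large-sample form appropriate for cohorts of this size.
#'
#' @param x,y Numeric vectors of equal length, at least 3.
#' @return Tibble with `rho`, `p.value`, `n`.
#' @examples
#' spearman(c(1, 2, 3), c(3, 1, 2)) # rho = -0.5
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- stats::complete.cases(x, y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) abort("need at least 3 complete pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    abort("rho undefined: zero rank variance")
  }
  rho <- cor(x, y, method = "spearman")
  p <- spearman_p(rho, n)
  tibble::tibble(rho = rho, p.value = p, n = n)
}

spearman_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t_stat <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * pt(-abs(t_stat), df = n - 2)
}

# Compact letter display by the insert-and-absorb algorithm: start from one
# set containing all groups; every significant pair splits the sets that
# contain both members; subset sets are absorbed. Groups sharing a letter
# were not significantly different in the pairwise step.
compact_letters <- function(p_matrix, alpha = 0.05) {
  groups <- rownames(p_matrix)
  sets <- list(groups)
  pairs <- which(upper.tri(p_matrix), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- groups[pairs[r, 1]]
    j <- groups[pairs[r, 2]]
    pij <- p_matrix[pairs[r, 1], pairs[r, 2]]
    if (is.na(pij) || pij >= alpha) next
    new_sets <- list()
    for (s in sets) {
      if (i %in% s && j %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, i)), list(setdiff(s, j)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb subsets
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) {
      for (b in seq_along(new_sets)) {
        if (a != b && keep[b] &&
            all(new_sets[[a]] %in% new_sets[[b]]) &&
            (length(new_sets[[a]]) < length(new_sets[[b]]) || a > b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    sets <- new_sets[keep]
  }
  # order letters by the first group they contain
  first_pos <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_pos)]
  vapply(groups, function(g) {
    paste0(letters[which(vapply(sets, function(s) g %in% s, logical(1)))],
           collapse = "")
  }, character(1))
}

#' Per-feature Kruskal-Wallis comparisons among enterotypes
#'
#' Runs one Kruskal-Wallis test per feature (taxon relative abundance,
#' alpha-diversity metric, phenotype or covariate) across enterotype
#' groups and summarizes each group with mean, SEM and median. Raw
#' p-values are reported as measured; Benjamini-Hochberg q-values are
#' added across the features of the call (one feature family per call).
#' Compact letter displays come from all pairwise Mann-Whitney tests at
#' `alpha` after BH correction across the pairs of each feature: groups
#' sharing a letter were not significantly different.
#'
#' Features for which any group has fewer than 2 observations are skipped
#' with a warning.
#'
#' @param data Wide tibble: first column sample ids, remaining numeric
#'   feature columns.
#' @param labels Enterotype labels (`sample_id`, `enterotype` tibble).
#' @param alpha Significance level for the letter display (default 0.05).
#' @return Tibble with one row per feature: `feature`, `statistic`, `df`,
#'   `p.value`, `q.value`, then per-group columns `mean_ET<g>`,
#'   `sem_ET<g>`, `median_ET<g>`, `letter_ET<g>`.
#' @seealso [kruskal_wallis()], [alpha_diversity()]
#' @export
per_feature_group_tests <- function(data, labels, alpha = 0.05) {
  lab <- as_label_vector(labels)
  ids <- as.character(data[[1]])
  if (!all(ids %in% names(lab))) {
    if (length(lab) == length(ids) && is.null(names(lab))) {
      names(lab) <- ids
    } else {
      missing <- setdiff(ids, names(lab))
      if (length(missing) > 0) {
        abort(paste0("samples without labels: ", paste(head(missing, 5), collapse = ", ")))
      }
    }
  }
  g <- factor(lab[ids])
  features <- names(data)[-1]
  group_names <- paste0("ET", levels(g))
  rows <- purrr::map(features, function(f) {
    x <- data[[f]]
    sizes <- tapply(x, g, function(v) sum(!is.na(v)))
    if (any(sizes < 2)) {
      warn(sprintf("feature '%s' skipped: a group has fewer than 2 observations", f))
      return(NULL)
    }
    kw <- kruskal_wallis(x, g)
    stats_by_group <- tibble::tibble(
      group = group_names,
      mean = as.numeric(tapply(x, g, mean)),
      sem = as.numeric(tapply(x, g, function(v) sd(v) / sqrt(length(v)))),
      median = as.numeric(tapply(x, g, median))
    )
    # pairwise Mann-Whitney with BH across the pairs of this feature
    lev <- levels(g)
    pm <- matrix(NA_real_, nlevels(g), nlevels(g),
                 dimnames = list(group_names, group_names))
    pair_idx <- combn(nlevels(g), 2)
    raw <- apply(pair_idx, 2, function(ij) {
      xi <- x[g == lev[ij[1]]]
      xj <- x[g == lev[ij[2]]]
      if (length(unique(c(xi, xj))) == 1) return(1)
      suppressWarnings(wilcox.test(xi, xj)$p.value)
    })
    adj <- p.adjust(raw, method = "BH")
    for (c2 in seq_len(ncol(pair_idx))) {
      pm[pair_idx[1, c2], pair_idx[2, c2]] <- adj[c2]
      pm[pair_idx[2, c2], pair_idx[1, c2]] <- adj[c2]
    }
    lets <- compact_letters(pm, alpha = alpha)
    tibble::tibble(
      feature = f, statistic = kw$statistic, df = kw$df, p.value = kw$p.value,
      group = stats_by_group$group, mean = stats_by_group$mean,
      sem = stats_by_group$sem, median = stats_by_group$median,
      letter = unname(lets)
    )
  })
  long <- dplyr::bind_rows(rows)
  if (nrow(long) == 0) abort("no feature had enough observations per group")
  per_feature <- dplyr::distinct(long, .data$feature, .data$statistic,
                                 .data$df, .data$p.value)
  per_feature$q.value <- p.adjust(per_feature$p.value, method = "BH")
  wide <- tidyr::pivot_wider(
    long,
    id_cols = "feature",
    names_from = "group",
    values_from = c("mean", "sem", "median", "letter"),
    names_glue = "{.value}_{group}"
  )
  dplyr::left_join(per_feature, wide, by = "feature")
}

#' Spearman co-occurrence among the predominant taxa
#'
#' Selects the `top_n` most abundant taxa by mean relative abundance and
#' computes all pairwise Spearman rank correlations of their per-sample
#' abundances — the co-occurrence structure among dominant genera.
#' Constant taxa get `NA` correlations and are flagged rather than being
#' dropped silently.
#'
#' @param table Abundance tibble.
#' @param top_n How many of the most abundant taxa to correlate
#'   (default 12, the number of predominant genera a cohort of this kind
#'   typically displays).
#' @return Object of class `cooccurrence`: list with `matrix` (symmetric
#'   rho matrix, unit diagonal), `pairs` (long tibble `taxon_a`,
#'   `taxon_b`, `rho`, `p.value`, `q.value` BH-adjusted across pairs) and
#'   `constant_taxa`.
#' @export
cooccurrence_matrix <- function(table, top_n = 12) {
  rel <- normalize_relative(table)
  mat <- as_abundance_matrix(rel)
  if (top_n > ncol(mat)) abort("top_n exceeds the number of taxa")
  top <- names(sort(colMeans(mat), decreasing = TRUE))[seq_len(top_n)]
  sub <- mat[, top, drop = FALSE]
  # constant within floating-point jitter of the compositional closure
  constant <- top[apply(sub, 2, function(v) {
    diff(range(v)) <= 1e-12 * max(abs(v), 1e-300)
  })]
  rho <- suppressWarnings(cor(sub, method = "spearman"))
  diag(rho) <- 1
  rho[constant, ] <- NA_real_
  rho[, constant] <- NA_real_
  diag(rho) <- ifelse(top %in% constant, NA_real_, 1)
  n <- nrow(sub)
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  pairs <- tibble::tibble(
    taxon_a = top[idx[, 1]],
    taxon_b = top[idx[, 2]],
    rho = rho[idx]
  )
  pairs$p.value <- vapply(pairs$rho, function(r) {
    if (is.na(r)) NA_real_ else spearman_p(r, n)
  }, numeric(1))
  pairs$q.value <- p.adjust(pairs$p.value, method = "BH")
  structure(list(matrix = rho, pairs = pairs, constant_taxa = constant,
                 n_samples = n),
            class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  cat(sprintf("Spearman co-occurrence among %d taxa (%d samples)\n",
              nrow(x$matrix), x$n_samples))
  strongest <- dplyr::arrange(x$pairs, dplyr::desc(abs(.data$rho)))
  print(head(strongest, 5))
  invisible(x)
}

#' Rank candidate taxa by association with butyrate
#'
#' For each candidate butyrate-producer taxon, computes the Spearman
#' correlation of its relative abundance with fecal butyrate content and
#' with the log10 copy numbers of the two terminal butyrate-synthesis
#' genes, butyrate kinase (Buk) and butyryl-CoA:acetate-CoA transferase
#' (But). Rows are sorted by the butyrate correlation, strongest first.
#' The gene-phenotype correlations rho(butyrate, Buk) and
#' rho(butyrate, But) are reported alongside in `gene_correlations`.
#'
#' @param table Abundance tibble containing the candidate taxa.
#' @param phenotype Phenotype tibble with `butyrate_mg_per_g`,
#'   `buk_log10_copies`, `but_log10_copies`.
#' @param candidate_taxa Character vector of taxon names; candidates
#'   absent from the table are reported in `skipped`, not fatal.
#' @return Object of class `butyrate_ranking`: list with `ranking`
#'   (tibble `taxon`, `rho_butyrate`, `p_butyrate`, `rho_buk`, `rho_but`),
#'   `gene_correlations` (tibble `gene`, `rho`, `p.value`), `skipped`,
#'   `n_samples`.
#' @export
phenotype_association_ranking <- function(table, phenotype, candidate_taxa) {
  aligned <- align_tables(table, phenotype)
  rel <- normalize_relative(aligned$abundance)
  mat <- as_abundance_matrix(rel)
  phen <- aligned$phenotype
  needed <- c("butyrate_mg_per_g", "buk_log10_copies", "but_log10_copies")
  missing_cols <- setdiff(needed, names(phen))
  if (length(missing_cols) > 0) {
    abort(paste0("phenotype table lacks column(s): ", paste(missing_cols, collapse = ", ")))
  }
  if (nrow(mat) < 3) abort("fewer than 3 complete sample pairs after alignment")
  skipped <- setdiff(candidate_taxa, colnames(mat))
  if (length(skipped) > 0) {
    warn(paste0("candidate taxa absent from table: ", paste(skipped, collapse = ", ")))
  }
  present <- intersect(candidate_taxa, colnames(mat))
  if (length(present) == 0) abort("no candidate taxon present in the table")
  rows <- purrr::map(present, function(tx) {
    sb <- spearman(mat[, tx], phen$butyrate_mg_per_g)
    tibble::tibble(
      taxon = tx,
      rho_butyrate = sb$rho,
      p_butyrate = sb$p.value,
      rho_buk = spearman(mat[, tx], phen$buk_log10_copies)$rho,
      rho_but = spearman(mat[, tx], phen$but_log10_copies)$rho
    )
  })
  ranking <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$rho_butyrate))
  gene_correlations <- dplyr::bind_rows(
    cbind(tibble::tibble(gene = "Buk"),
          spearman(phen$butyrate_mg_per_g, phen$buk_log10_copies)[c("rho", "p.value")]),
    cbind(tibble::tibble(gene = "But"),
          spearman(phen$butyrate_mg_per_g, phen$but_log10_copies)[c("rho", "p.value")])
  )
  structure(list(ranking = ranking,
                 gene_correlations = tibble::as_tibble(gene_correlations),
                 skipped = skipped, n_samples = nrow(mat)),
            class = "butyrate_ranking")
}

#' @export
print.butyrate_ranking <- function(x, ...) {
  cat(sprintf("Butyrate association ranking (%d samples)\n", x$n_samples))
  print(x$ranking)
  cat("\nGene copy vs butyrate:\n")
  print(x$gene_correlations)
  if (length(x$skipped) > 0) {
    cat("skipped (absent from table):", paste(x$skipped, collapse = ", "), "\n")
  }
  invisible(x)
}
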