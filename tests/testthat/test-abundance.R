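test_that("TSV reader detects units, validates ids and values", {
  dir <- withr::local_tempdir()
  path <- file.path(dir, "counts.tsv")

  readr::write_tsv(toy_counts(), path)
  tab <- read_abundance_table(path)
  expect_identical(dim(tab), c(3L, 4L))
  expect_identical(attr(tab, "unit"), "counts")

  rel <- normalize_relative(toy_counts())
  rel_path <- file.path(dir, "rel.tsv")
  readr::write_tsv(rel, rel_path)
  expect_identical(attr(read_abundance_table(rel_path), "unit"), "relative")

  bad <- toy_counts()
  bad$Bacteroides[2] <- -1
  readr::write_tsv(bad, file.path(dir, "neg.tsv"))
  expect_error(read_abundance_table(file.path(dir, "neg.tsv")), "negative abundance")

  dup <- toy_counts()
  dup$sample_id <- c("a", "a", "c")
  readr::write_tsv(dup, file.path(dir, "dup.tsv"))
  expect_error(read_abundance_table(file.path(dir, "dup.tsv")), "duplicate sample ids")

  writeLines(c("id\tx\ty", "a\t1\t2", "b\t3"), file.path(dir, "ragged.tsv"))
  expect_error(
    suppressWarnings(read_abundance_table(file.path(dir, "ragged.tsv"))),
    "ragged|missing"
  )

  # neither integral nor row-normalized
  amb <- toy_counts()
  amb$Bacteroides <- amb$Bacteroides + 0.3
  readr::write_tsv(amb, file.path(dir, "amb.tsv"))
  expect_error(read_abundance_table(file.path(dir, "amb.tsv")), "unit")
})

test_that("read-write round trips are value identical for TSV and BIOM", {
  dir <- withr::local_tempdir()
  tab <- toy_counts()

  tsv <- file.path(dir, "t.tsv")
  write_abundance_table(tab, tsv)
  back <- read_abundance_table(tsv)
  expect_equal(as_abundance_matrix(back), as_abundance_matrix(tab))

  biom <- file.path(dir, "t.biom")
  write_abundance_table(tab, biom, format = "biom_json")
  back2 <- read_abundance_table(biom, format = "biom_json")
  expect_equal(
    as_abundance_matrix(back2)[tab$sample_id, names(tab)[-1]],
    as_abundance_matrix(tab)
  )

  # taxa-rows orientation transposes on read
  t_tab <- tibble::as_tibble(t(as_abundance_matrix(tab)), rownames = "taxon_id")
  t_path <- file.path(dir, "taxa_rows.tsv")
  readr::write_tsv(t_tab, t_path)
  back3 <- read_abundance_table(t_path, orientation = "taxa_rows")
  expect_equal(as_abundance_matrix(back3), as_abundance_matrix(tab))
})

test_that("normalize_relative is idempotent, scale invariant, and names bad rows", {
  tab <- toy_counts()
  rel <- normalize_relative(tab)
  m <- as_abundance_matrix(rel)
  expect_equal(unname(rowSums(m)), rep(1, 3), tolerance = 1e-12)
  expect_equal(m["a", ], c(Bacteroides = 0.4, Lactobacillus = 0.4, Prevotella = 0.2))

  # idempotent
  expect_equal(as_abundance_matrix(normalize_relative(rel)), m)

  # row scaling does not change the output
  scaled <- tab
  scaled[2, -1] <- scaled[2, -1] * 17
  expect_equal(as_abundance_matrix(normalize_relative(scaled)), m)

  zero <- tab
  zero[2, -1] <- 0
  expect_error(normalize_relative(zero), "all-zero sample row.*b")
})

test_that("low-abundance filter keeps taxa by mean or prevalence and re-normalizes", {
  # 5 taxa, one with mean relative abundance 5e-5
  tab <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    A = c(0.3, 0.3, 0.3, 0.3), B = c(0.3, 0.3, 0.3, 0.3),
    C = c(0.2, 0.2, 0.2, 0.2), D = c(0.19995, 0.19995, 0.19995, 0.19995),
    E = rep(5e-5, 4)
  )
  out <- filter_low_abundance(tab, min_mean_rel = 1e-4)
  expect_identical(attr(out, "removed_taxa"), "E")
  expect_identical(ncol(out), 5L) # sample_id + 4 taxa
  expect_equal(rowSums(as_abundance_matrix(out)), setNames(rep(1, 4), tab$sample_id))

  # thresholds (0, 0) are the identity
  ident <- filter_low_abundance(tab)
  expect_identical(names(ident), names(tab))
  expect_identical(attr(ident, "removed_taxa"), character(0))

  # prevalence rule rescues a rare-but-prevalent taxon only when active
  kept <- filter_low_abundance(tab, min_mean_rel = 1e-4, min_prevalence = 0.5)
  expect_false("E" %in% attr(kept, "removed_taxa"))

  expect_error(filter_low_abundance(tab, min_mean_rel = 10), "removed all taxa")
})

test_that("phenotype alignment inner-joins and reports drops", {
  ab <- toy_counts()
  ph <- tibble::tibble(
    sample_id = c("b", "c", "zz"),
    butyrate_mg_per_g = c(1, 2, 3),
    buk_log10_copies = c(7, 7.5, 8),
    but_log10_copies = c(8, 8.5, 9)
  )
  expect_message(aligned <- align_tables(ab, ph), "1 abundance-only and 1 phenotype-only")
  expect_identical(aligned$abundance$sample_id, c("b", "c"))
  expect_identical(aligned$phenotype$sample_id, c("b", "c"))
  expect_identical(aligned$dropped_abundance, "a")
  expect_identical(aligned$dropped_phenotype, "zz")
})

test_that("labels round-trip through TSV", {
  dir <- withr::local_tempdir()
  lab <- tibble::tibble(sample_id = c("a", "b"), enterotype = c(1L, 2L))
  p <- file.path(dir, "labels.tsv")
  write_labels(lab, p)
  expect_identical(read_labels(p), lab)
})
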