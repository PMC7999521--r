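test_that("default config encodes the planted cohort conditions", {
  cfg <- default_config()
  expect_identical(cfg$n_samples, 105L)
  expect_identical(cfg$k, 3L)
  expect_equal(sum(cfg$mixing), 1)
  expect_equal(rowSums(cfg$profiles), rep(1, 3), tolerance = 1e-12)
  expect_true(all(cfg$profiles > 0))
  # driver-genus expected relative abundances (up to the tiny-floor renormalization)
  expect_equal(unname(cfg$profiles[1, "Lactobacillus"]), 0.1439, tolerance = 1e-3)
  expect_equal(unname(cfg$profiles[1, "Clostridium sensu stricto 1"]), 0.1341, tolerance = 1e-3)
  expect_equal(unname(cfg$profiles[2, "Clostridium sensu stricto 1"]), 0.1749, tolerance = 1e-3)
  expect_equal(unname(cfg$profiles[2, "Bifidobacterium"]), 0.1178, tolerance = 1e-3)
  expect_equal(unname(cfg$profiles[3, "Bacteroides"]), 0.1817, tolerance = 1e-3)
  # all nine candidate producer genera are on the roster, elevated in component 3
  expect_true(all(producer_candidates %in% cfg$taxa))
  strong <- c("Faecalibacterium", "Butyricicoccus", "Eubacterium hallii group",
              "Butyricimonas", "Blautia", "Anaerostipes")
  expect_true(all(cfg$profiles[3, strong] > cfg$profiles[1, strong]))
  expect_true(all(cfg$profiles[3, strong] > cfg$profiles[2, strong]))
})

test_that("generate_cohort is deterministic and respects the count model", {
  cfg <- default_config(seed = 123)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)

  counts <- as_abundance_matrix(a$abundance)
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
  depths <- rowSums(counts)
  expect_true(all(depths >= 40000 - 1 & depths <= 100000 + 1))
  expect_identical(nrow(counts), 105L)
  expect_identical(a$truth$seed, 123L)

  # component sizes near the mixing expectation (~35 each at n = 105)
  sizes <- table(a$truth$component_labels$component)
  expect_true(all(sizes > 15 & sizes < 55))

  expect_error(generate_cohort({
    cfg_bad <- cfg; cfg_bad$concentration <- -1; cfg_bad
  }), "concentration")
})

test_that("high concentration and depth collapse samples onto the component mean", {
  cfg <- default_config(n_samples = 12, seed = 8, concentration = 1e6)
  cfg$depth_range <- c(1e6, 1e6)
  cfg$latent_loadings <- cfg$latent_loadings[0]
  co <- generate_cohort(cfg)
  rel <- as_abundance_matrix(normalize_relative(co$abundance))
  comp <- co$truth$component_labels$component
  for (i in seq_len(nrow(rel))) {
    expect_lt(max(abs(rel[i, ] - cfg$profiles[comp[i], ])), 0.01)
  }
})

test_that("gene-copy couplings land in their calibrated windows across seeds", {
  rb <- rk <- numeric(20)
  for (s in 1:20) {
    co <- generate_cohort(default_config(seed = s))
    rb[s] <- spearman(co$phenotype$but_log10_copies,
                      co$phenotype$butyrate_mg_per_g)$rho
    rk[s] <- spearman(co$phenotype$buk_log10_copies,
                      co$phenotype$butyrate_mg_per_g)$rho
  }
  expect_true(all(rb > 0.6 & rb < 0.85))
  expect_true(all(rk > 0.35 & rk < 0.6))
})

test_that("null cohort carries no cluster structure or phenotype coupling", {
  co <- null_cohort(default_config(n_samples = 60, seed = 30))
  expect_true(all(co$truth$component_labels$component == 1))

  # prediction strength at K >= 2 stays below the acceptance threshold
  ps2 <- vapply(1:10, function(s) {
    nc <- null_cohort(default_config(n_samples = 60, seed = s))
    as.numeric(prediction_strength(nc$abundance, 2, n_repeats = 8, seed = s))
  }, numeric(1))
  expect_lt(mean(ps2), 0.8)

  # butyrate is independent of the producer genera
  pvals <- vapply(1:10, function(s) {
    nc <- null_cohort(default_config(seed = s + 100))
    rel <- as_abundance_matrix(normalize_relative(nc$abundance))
    spearman(rel[, "Faecalibacterium"], nc$phenotype$butyrate_mg_per_g)$p.value
  }, numeric(1))
  expect_gt(mean(pvals > 0.05), 0.7)
})

test_that("planted co-occurrence group and cross-component driver antagonism are recovered", {
  co <- generate_cohort(default_config(seed = 1))
  cooc <- cooccurrence_matrix(co$abundance, top_n = 12)
  m <- cooc$matrix
  grp <- c("Clostridium sensu stricto 1", "Terrisporobacter",
           "Turicibacter", "Romboutsia")
  expect_true(all(grp %in% rownames(m)))
  pairs <- m[grp, grp][upper.tri(matrix(0, 4, 4))]
  expect_gt(mean(pairs), 0.6)
  expect_true(all(pairs > 0.4))
  # drivers of different components anti-correlate across the cohort
  expect_lt(m["Lactobacillus", "Bacteroides"], 0)
  expect_lt(m["Bifidobacterium", "Bacteroides"], 0)
})
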