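test_that("kruskal_wallis reproduces the rank formula and edge cases", {
  res <- kruskal_wallis(1:9, rep(1:3, each = 3))
  expect_equal(res$statistic, 7.2, tolerance = 1e-12)
  expect_equal(res$p.value, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-12)

  # all values identical: defined as H = 0, p = 1
  flat <- kruskal_wallis(rep(2, 9), rep(1:3, each = 3))
  expect_identical(flat$statistic, 0)
  expect_identical(flat$p.value, 1)

  # two groups, no ties: equals the squared standardized rank-sum statistic
  set.seed(51)
  x <- sample(1:20, 12)
  g <- rep(1:2, each = 6)
  kw <- kruskal_wallis(x, g)$statistic
  r <- rank(x)
  n <- 12; n1 <- 6
  z <- (sum(r[g == 1]) - n1 * (n + 1) / 2) / sqrt(n1 * n1 * (n + 1) / 12)
  expect_equal(kw, z^2, tolerance = 1e-10)

  expect_error(kruskal_wallis(1:5, rep(1, 5)), "two groups")
})

test_that("kruskal_wallis is invariant under strictly monotone transforms", {
  set.seed(52)
  x <- rnorm(30)
  g <- rep(1:3, each = 10)
  h0 <- kruskal_wallis(x, g)$statistic
  expect_equal(kruskal_wallis(exp(x), g)$statistic, h0, tolerance = 1e-12)
  expect_equal(kruskal_wallis(x^3, g)$statistic, h0, tolerance = 1e-12)
})

test_that("spearman matches the d-squared formula and the midrank oracle", {
  res <- spearman(c(1, 2, 3), c(3, 1, 2))
  expect_equal(res$rho, -0.5, tolerance = 1e-12) # 1 - 6*6/(3*8)

  expect_equal(spearman(1:10, (1:10)^3)$rho, 1)

  # ties: equals Pearson on midranks
  set.seed(53)
  x <- sample(1:5, 20, replace = TRUE)
  y <- sample(1:4, 20, replace = TRUE) + 0.1 * x
  oracle <- cor(rank(x), rank(y))
  expect_equal(spearman(x, y)$rho, oracle, tolerance = 1e-12)

  # t-approximation p-value
  r <- spearman(x, y)
  t_stat <- r$rho * sqrt((20 - 2) / (1 - r$rho^2))
  expect_equal(r$p.value, 2 * pt(-abs(t_stat), 18), tolerance = 1e-12)

  # monotone-transform invariance of both arguments
  xr <- rnorm(15); yr <- rnorm(15)
  expect_equal(spearman(exp(xr), yr)$rho, spearman(xr, yr)$rho, tolerance = 1e-12)
  expect_equal(spearman(xr, yr^3)$rho, spearman(xr, yr)$rho, tolerance = 1e-12)

  expect_error(spearman(rep(1, 5), 1:5), "zero rank variance")
  expect_error(spearman(1:2, 1:2), "at least 3")
})

test_that("per-feature tests recover a planted single-group effect with letters", {
  set.seed(54)
  n <- 60
  g <- rep(1:3, each = 20)
  dat <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    shifted = rnorm(n) + ifelse(g == 3, 3, 0),
    flat = rep(1, n),
    noise = rnorm(n)
  )
  labels <- tibble::tibble(sample_id = dat$sample_id, enterotype = g)
  res <- per_feature_group_tests(dat, labels)

  shifted <- res[res$feature == "shifted", ]
  expect_lt(shifted$p.value, 1e-4)
  expect_identical(shifted$letter_ET1, shifted$letter_ET2)
  expect_false(shifted$letter_ET3 == shifted$letter_ET1)

  flat <- res[res$feature == "flat", ]
  expect_identical(flat$p.value, 1)
  expect_identical(unique(c(flat$letter_ET1, flat$letter_ET2, flat$letter_ET3)), "a")

  # BH monotone in p, bounded by 1, identity at m = 1
  expect_true(all(res$q.value >= res$p.value - 1e-15))
  expect_true(all(res$q.value <= 1))
  one <- per_feature_group_tests(dat[c("sample_id", "noise")], labels)
  expect_identical(one$q.value, one$p.value)

  # group means/SEMs mirror direct computation
  expect_equal(shifted$mean_ET3, mean(dat$shifted[g == 3]), tolerance = 1e-12)
  expect_equal(shifted$sem_ET1,
               sd(dat$shifted[g == 1]) / sqrt(20), tolerance = 1e-12)
  expect_equal(shifted$median_ET2, median(dat$shifted[g == 2]), tolerance = 1e-12)

  # a group with < 2 observations skips the feature with a warning
  small <- tibble::tibble(sample_id = paste0("s", 1:5), f = rnorm(5))
  small_lab <- tibble::tibble(sample_id = small$sample_id,
                              enterotype = c(1, 1, 2, 2, 3))
  expect_warning(expect_error(per_feature_group_tests(small, small_lab),
                              "no feature"),
                 "fewer than 2")
})

test_that("compact letters bridge non-significant chains", {
  # 1 vs 3 significant, 1-2 and 2-3 not: a / ab / b
  pm <- matrix(c(NA, 0.8, 0.01,
                 0.8, NA, 0.6,
                 0.01, 0.6, NA), 3, 3,
               dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  lets <- enterotyper:::compact_letters(pm, alpha = 0.05)
  expect_identical(unname(lets), c("a", "ab", "b"))
  # all different
  pm2 <- pm; pm2[] <- 0.001; diag(pm2) <- NA
  expect_identical(sort(unname(enterotyper:::compact_letters(pm2, 0.05))),
                   c("a", "b", "c"))
})

test_that("co-occurrence selects the most abundant taxa and flags constants", {
  set.seed(55)
  n <- 40
  # rows sum to 1 so the constant column survives compositional closure
  w <- matrix(rgamma(n * 3, 4), n)
  tiny <- runif(n, 0.001, 0.003)
  varying <- (1 - 0.008 - tiny) * w / rowSums(w)
  tab <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    big_a = varying[, 1],
    big_b = varying[, 2],
    mid = varying[, 3],
    rare = rep(0.008, n), # constant relative abundance
    tiny = tiny
  )
  cooc <- cooccurrence_matrix(tab, top_n = 4)
  expect_identical(sort(rownames(cooc$matrix)),
                   sort(c("big_a", "big_b", "mid", "rare")))
  expect_identical(diag(cooc$matrix)[["big_a"]], 1)
  expect_true(isSymmetric(cooc$matrix))
  expect_identical(cooc$constant_taxa, "rare")
  expect_true(all(is.na(cooc$matrix["rare", ])))

  expect_error(cooccurrence_matrix(tab, top_n = 10), "exceeds")
})

test_that("strictly co-monotone taxa correlate at 1 after compositional closure", {
  n <- 20
  up <- seq_len(n)
  tab <- tibble::tibble(
    sample_id = paste0("s", 1:n),
    x = up, y = 2 * up,
    filler = rep(100, n)
  )
  cooc <- cooccurrence_matrix(tab, top_n = 3)
  expect_equal(cooc$matrix["x", "y"], 1)
})

test_that("phenotype ranking orders taxa by butyrate correlation and reports gene couplings", {
  co <- generate_cohort(default_config(seed = 2))
  rk <- suppressMessages(
    phenotype_association_ranking(co$abundance, co$phenotype, producer_candidates)
  )
  expect_identical(rk$ranking$taxon[1], "Faecalibacterium")
  expect_true(all(diff(rk$ranking$rho_butyrate) <= 0))
  g <- glance(rk)
  expect_gt(g$rho_butyrate_but, g$rho_butyrate_buk)

  # absent candidate is reported, not fatal
  expect_warning(
    rk2 <- suppressMessages(phenotype_association_ranking(
      co$abundance, co$phenotype, c("Faecalibacterium", "NotARealGenus"))),
    "NotARealGenus"
  )
  expect_identical(rk2$skipped, "NotARealGenus")
  expect_identical(nrow(rk2$ranking), 1L)

  # noise-free monotone coupling gives rho = 1
  n <- 30
  tab <- tibble::tibble(sample_id = paste0("s", 1:n),
                        A = seq_len(n), B = rep(50, n))
  phen <- tibble::tibble(
    sample_id = tab$sample_id,
    butyrate_mg_per_g = (seq_len(n) / (seq_len(n) + 50))^2, # monotone in A's share
    buk_log10_copies = rnorm(n, 7), but_log10_copies = rnorm(n, 8)
  )
  rk3 <- phenotype_association_ranking(tab, phen, "A")
  expect_equal(rk3$ranking$rho_butyrate, 1)
})

test_that("null labels keep the type-I error of per-feature tests near nominal", {
  set.seed(56)
  co <- null_cohort(default_config(n_samples = 60, seed = 77))
  rel <- normalize_relative(co$abundance)
  labels <- tibble::tibble(sample_id = rel$sample_id,
                           enterotype = sample(1:3, 60, replace = TRUE))
  res <- per_feature_group_tests(rel, labels)
  expect_lt(mean(res$p.value < 0.05), 0.25)
  # alpha diversity under null labels: everyone shares a letter, usually
  ad <- alpha_diversity(co$abundance)
  res_ad <- per_feature_group_tests(ad, labels)
  expect_true(all(c("letter_ET1", "letter_ET2", "letter_ET3") %in% names(res_ad)))
})
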