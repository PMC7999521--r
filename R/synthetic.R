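# Synthetic cohort generator: Dirichlet-multinomial genus tables with
# planted enterotypes and a coupled butyrate phenotype.

# Genus roster: the cohort's dominant genera, the nine butyrate-producer
# candidates, and per-phylum tail genera carrying the residual mass.
producer_genera <- c(
  "Faecalibacterium", "Butyricicoccus", "Eubacterium hallii group",
  "Butyricimonas", "Blautia", "Anaerostipes", "Coprococcus",
  "Oscillospira", "Roseburia"
)

firmicutes_tail <- paste0("Firmicutes_genus_", sprintf("%02d", 1:10))
bacteroidetes_tail <- paste0("Bacteroidetes_genus_", sprintf("%02d", 1:3))
actinobacteria_tail <- paste0("Actinobacteria_genus_", sprintf("%02d", 1:3))
proteobacteria_tail <- paste0("Proteobacteria_genus_", sprintf("%02d", 1:3))

# Component mean profiles of the 3 planted enterotypes over a 41-genus
# roster. Per-enterotype phylum totals and the driver-genus means are the
# emulated cohort's printed composition; the residual mass of each phylum
# decays geometrically over tail genera whose rank order differs per
# enterotype (identity / reversed / half-rotated), emulating the
# genus-level reordering real community types display.
component_profiles <- function(decay = 0.7) {
  taxa <- c("Clostridium sensu stricto 1", "Lactobacillus", "Bifidobacterium",
            "Bacteroides", "Streptococcus", "Terrisporobacter", "Turicibacter",
            "Romboutsia", "Christensenellaceae R-7 group",
            "Prevotellaceae NK3B31 group", "Prevotella", "Treponema",
            producer_genera, firmicutes_tail, bacteroidetes_tail,
            actinobacteria_tail, proteobacteria_tail, "Acidobacteria_genus_01")
  p <- matrix(0, 3, length(taxa), dimnames = list(NULL, taxa))
  phyla <- rbind(
    Firmicutes = c(76.5944, 63.8640, 60.4627),
    Bacteroidetes = c(14.838, 8.2120, 29.3014),
    Actinobacteria = c(1.6287, 15.5593, 5.3892),
    Spirochaetes = c(4.5188, 2.5254, 1.3508),
    Proteobacteria = c(1.1146, 5.1483, 2.0045),
    Acidobacteria = c(0.1995, 1.8077, 0.0009)
  ) / 100
  phyla <- sweep(phyla, 2, colSums(phyla), "/")
  # drivers
  p[, "Clostridium sensu stricto 1"] <- c(0.1341, 0.1749, 0.060)
  p[, "Lactobacillus"] <- c(0.1439, 0.050, 0.040)
  p[, "Bifidobacterium"] <- c(0.015, 0.1178, 0.020)
  p[, "Bacteroides"] <- c(0.030, 0.015, 0.1817)
  # named mid-rank genera; the Clostridium group tracks the driver
  p[, "Streptococcus"] <- c(0.070, 0.045, 0.030)
  p[, "Terrisporobacter"] <- c(0.055, 0.060, 0.020)
  p[, "Turicibacter"] <- c(0.050, 0.055, 0.015)
  p[, "Romboutsia"] <- c(0.050, 0.055, 0.018)
  p[, "Christensenellaceae R-7 group"] <- c(0.025, 0.015, 0.035)
  p[, "Prevotellaceae NK3B31 group"] <- c(0.035, 0.015, 0.045)
  p[, "Prevotella"] <- c(0.025, 0.010, 0.040)
  p[, "Treponema"] <- phyla["Spirochaetes", ]
  # butyrate producers: elevated in component 3
  producers <- rbind(
    c(0.010, 0.004, 0.030), c(0.006, 0.003, 0.018), c(0.005, 0.0025, 0.015),
    c(0.004, 0.002, 0.012), c(0.008, 0.004, 0.020), c(0.004, 0.002, 0.010),
    c(0.005, 0.005, 0.006), c(0.004, 0.004, 0.004), c(0.006, 0.006, 0.007)
  )
  rownames(producers) <- producer_genera
  for (g in producer_genera) p[, g] <- producers[g, ]

  geom_fill <- function(total, k, ratio) {
    w <- ratio^(0:(k - 1))
    total * w / sum(w)
  }
  firm_named <- c("Clostridium sensu stricto 1", "Lactobacillus",
                  "Streptococcus", "Terrisporobacter", "Turicibacter",
                  "Romboutsia", "Christensenellaceae R-7 group",
                  setdiff(producer_genera, "Butyricimonas"))
  bact_named <- c("Bacteroides", "Prevotellaceae NK3B31 group", "Prevotella",
                  "Butyricimonas")
  tail_order <- function(v, et) {
    switch(et, v, rev(v),
           v[((seq_along(v) + floor(length(v) / 2) - 1) %% length(v)) + 1])
  }
  for (et in 1:3) {
    p[et, tail_order(firmicutes_tail, et)] <-
      geom_fill(phyla["Firmicutes", et] - sum(p[et, firm_named]),
                length(firmicutes_tail), decay)
    p[et, tail_order(bacteroidetes_tail, et)] <-
      geom_fill(phyla["Bacteroidetes", et] - sum(p[et, bact_named]),
                length(bacteroidetes_tail), decay)
    p[et, tail_order(actinobacteria_tail, et)] <-
      geom_fill(phyla["Actinobacteria", et] - p[et, "Bifidobacterium"],
                length(actinobacteria_tail), decay)
    p[et, tail_order(proteobacteria_tail, et)] <-
      geom_fill(phyla["Proteobacteria", et], length(proteobacteria_tail), decay)
    p[et, "Acidobacteria_genus_01"] <- phyla["Acidobacteria", et]
  }
  stopifnot(min(p) >= 0)
  p <- pmax(p, 1e-5)
  p / rowSums(p)
}

#' Default synthetic cohort configuration
#'
#' Returns the configuration of the reference synthetic cohort: 105
#' samples in 3 latent enterotypes of equal expected size, a 41-genus
#' roster, Dirichlet-multinomial counts, and a butyrate phenotype driven
#' by the producer genera.
#'
#' Component mean profiles plant the driver-genus structure of the cohort
#' the generator emulates: enterotype 1 dominated by Lactobacillus
#' (expected relative abundance 0.1439) and Clostridium sensu stricto 1
#' (0.1341); enterotype 2 by Clostridium sensu stricto 1 (0.1749) and
#' Bifidobacterium (0.1178); enterotype 3 by Bacteroides (0.1817), with
#' the butyrate-producing genera elevated in enterotype 3 and
#' per-enterotype phylum totals matching the emulated composition.
#' A shared per-sample latent factor co-modulates the Clostridium group
#' (Clostridium sensu stricto 1, Terrisporobacter, Turicibacter,
#' Romboutsia) so their strong pairwise co-occurrence is part of the
#' planted structure.
#'
#' Butyrate (mg/g fresh feces) is a linear function of the producer-genus
#' relative abundances plus Gaussian noise, truncated at 0; the two
#' terminal-gene copy numbers are monotone functions of butyrate with
#' noise calibrated so their realized Spearman correlations with butyrate
#' approach the configured targets (defaults 0.7464 for But and 0.4905
#' for Buk). Sequencing depth is log-uniform between 40,000 and 100,000
#' reads.
#'
#' @param n_samples Cohort size (default 105).
#' @param k Number of planted components (default 3; at most 3).
#' @param concentration Dirichlet concentration (overdispersion)
#'   parameter; larger is tighter around the component mean. Default 130,
#'   a within-enterotype spread that keeps the three components clearly
#'   recoverable while leaving the clustering problem nontrivial.
#' @param seed Integer seed stored in the config; [generate_cohort()] uses
#'   it for every random draw.
#' @return Object of class `cohort_config` (a named list); editable before
#'   passing to [generate_cohort()].
#' @export
default_config <- function(n_samples = 105, k = 3, concentration = 130,
                           seed = 1) {
  if (k > 3) abort("default_config supports at most 3 components")
  profiles <- component_profiles()[seq_len(k), , drop = FALSE]
  profiles <- profiles / rowSums(profiles)
  taxa <- colnames(profiles)

  slopes <- setNames(rep(0, length(taxa)), taxa)
  slopes[c("Faecalibacterium", "Butyricicoccus", "Eubacterium hallii group",
           "Butyricimonas", "Blautia", "Anaerostipes")] <-
    c(60, 40, 35, 30, 25, 20)

  structure(list(
    n_samples = as.integer(n_samples),
    k = as.integer(k),
    mixing = rep(1 / k, k),
    taxa = taxa,
    profiles = profiles,
    concentration = concentration,
    depth_range = c(40000, 100000),
    latent_loadings = c("Clostridium sensu stricto 1" = 0.5,
                        "Terrisporobacter" = 1.0,
                        "Turicibacter" = 1.0,
                        "Romboutsia" = 1.0),
    butyrate_intercept = 0.5,
    butyrate_slopes = slopes,
    butyrate_noise_sd = 0.4,
    but_target_rho = 0.7464,
    buk_target_rho = 0.4905,
    but_scale = c(mean = 8.2, sd = 0.6),
    buk_scale = c(mean = 7.6, sd = 0.5),
    covariates = TRUE,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

validate_config <- function(config) {
  if (!inherits(config, "cohort_config")) abort("config must come from default_config()")
  if (config$n_samples < 1) abort("n_samples must be positive")
  if (config$concentration <= 0) abort("concentration must be positive")
  if (abs(sum(config$mixing) - 1) > 1e-9) abort("mixing proportions must sum to 1")
  if (nrow(config$profiles) != config$k) abort("profiles must have one row per component")
  if (any(config$profiles <= 0)) abort("component profiles must be strictly positive")
  if (!all(names(config$latent_loadings) %in% config$taxa)) {
    abort("latent_loadings name taxa missing from the roster")
  }
  invisible(config)
}

rdirichlet_one <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic enterotype cohort
#'
#' Draws, per sample: a latent component from the mixing proportions;
#' genus proportions from Dirichlet(concentration x component profile),
#' with the co-occurrence group jointly scaled by a shared log-normal
#' latent factor (per-genus loadings); a sequencing depth log-uniform in
#' the configured range; counts from a multinomial at that depth. The
#' butyrate phenotype is a linear function of producer-genus relative
#' abundances plus Gaussian noise (truncated at 0), and the two gene copy
#' numbers are Gaussian-noised monotone functions of butyrate calibrated
#' (through the Pearson-to-Spearman relation of the bivariate normal,
#' \eqn{r = 2 \sin(\pi \rho_s / 6)}) to hit the configured rank
#' correlations with butyrate.
#'
#' The same config (including its `seed`) reproduces the cohort
#' bit-exactly.
#'
#' @param config A `cohort_config`, e.g. [default_config()].
#' @return A list with `abundance` (counts tibble), `phenotype` (tibble
#'   with butyrate, gene copies, covariates) and `truth` (list: planted
#'   `component_labels` tibble, `dirichlet_alpha`, `depths`,
#'   `phenotype_coefficients`, `gene_copy_couplings`, `seed`).
#' @seealso [default_config()], [null_cohort()]
#' @export
generate_cohort <- function(config = default_config()) {
  validate_config(config)
  set.seed(config$seed)
  n <- config$n_samples
  taxa <- config$taxa
  comp <- sample.int(config$k, n, replace = TRUE, prob = config$mixing)
  alpha <- config$concentration * config$profiles
  props <- t(vapply(comp, function(z) rdirichlet_one(alpha[z, ]),
                    numeric(length(taxa))))
  colnames(props) <- taxa
  loadings <- config$latent_loadings
  if (length(loadings) > 0) {
    f <- rnorm(n)
    for (g in names(loadings)) {
      props[, g] <- props[, g] * exp(loadings[[g]] * f)
    }
    props <- props / rowSums(props)
  }
  depths <- round(exp(runif(n, log(config$depth_range[1]),
                            log(config$depth_range[2]))))
  counts <- t(vapply(seq_len(n),
                     function(i) rmultinom(1, depths[i], props[i, ])[, 1],
                     numeric(length(taxa))))
  colnames(counts) <- taxa
  rownames(counts) <- sprintf("S%03d", seq_len(n))

  rel <- counts / rowSums(counts)
  butyrate <- pmax(
    config$butyrate_intercept +
      as.numeric(rel %*% config$butyrate_slopes[taxa]) +
      rnorm(n, sd = config$butyrate_noise_sd),
    0
  )
  but <- gene_from_butyrate(butyrate, config$but_target_rho, config$but_scale)
  buk <- gene_from_butyrate(butyrate, config$buk_target_rho, config$buk_scale)

  phenotype <- tibble::tibble(
    sample_id = rownames(counts),
    butyrate_mg_per_g = butyrate,
    buk_log10_copies = buk,
    but_log10_copies = but
  )
  if (isTRUE(config$covariates)) {
    phenotype$water_pct <- rnorm(n, 72, 4)
    phenotype$ph <- rnorm(n, 7.3, 0.4)
    phenotype$organic_matter_g_kg <- rnorm(n, 307, 45)
    phenotype$total_n_g_kg <- rnorm(n, 43, 5)
    phenotype$total_p_g_kg <- rnorm(n, 29, 4)
  }

  list(
    abundance = as_abundance_tibble(counts),
    phenotype = phenotype,
    truth = list(
      component_labels = tibble::tibble(sample_id = rownames(counts),
                                        component = as.integer(comp)),
      dirichlet_alpha = alpha,
      depths = depths,
      phenotype_coefficients = list(
        intercept = config$butyrate_intercept,
        slopes = config$butyrate_slopes[config$butyrate_slopes != 0],
        noise_sd = config$butyrate_noise_sd
      ),
      gene_copy_couplings = c(But = config$but_target_rho,
                              Buk = config$buk_target_rho),
      seed = config$seed
    )
  )
}

# Gene copies as a monotone function of butyrate plus noise: take normal
# scores of the butyrate ranks and mix with Gaussian noise at the Pearson
# level matching the target Spearman correlation. The noise is
# orthogonalized against the scores so the realized coupling sits on the
# target instead of merely centering there.
gene_from_butyrate <- function(butyrate, target_rho, scale) {
  n <- length(butyrate)
  z <- qnorm((rank(butyrate, ties.method = "average") - 0.5) / n)
  z <- z / sd(z)
  e <- rnorm(n)
  e <- e - z * sum(e * z) / sum(z * z)
  e <- e / sd(e)
  r <- 2 * sin(pi * target_rho / 6)
  y <- r * z + sqrt(1 - r^2) * e
  scale[["mean"]] + scale[["sd"]] * y
}

#' Generate a structureless (null) cohort
#'
#' Single-component negative control: every sample is drawn from one
#' Dirichlet component (the mixture average of the configured profiles)
#' and butyrate is independent of all taxa. Used to check that the k
#' selection does not hallucinate clusters and that group tests hold
#' their type-I error.
#'
#' @inheritParams generate_cohort
#' @return Same shape as [generate_cohort()], with all component labels 1.
#' @export
null_cohort <- function(config = default_config()) {
  validate_config(config)
  pooled <- colSums(config$profiles * config$mixing)
  pooled <- pooled / sum(pooled)
  cfg <- config
  cfg$k <- 1L
  cfg$mixing <- 1
  cfg$profiles <- matrix(pooled, nrow = 1, dimnames = list(NULL, config$taxa))
  cfg$butyrate_intercept <- config$butyrate_intercept +
    sum(config$butyrate_slopes * pooled)
  cfg$butyrate_slopes <- setNames(rep(0, length(config$taxa)), config$taxa)
  class(cfg) <- "cohort_config"
  generate_cohort(cfg)
}
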