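# enterotyper

Enterotype discovery and butyrate-association analysis for 16S rRNA
microbiome cohorts, as a tidyverse-native R package.

Gut microbiome cohorts frequently stratify into a few discrete community
types ("enterotypes"), each dominated by different driver genera, and
enterotype membership can carry functional consequences — most notably
for butyrate, the four-carbon short-chain fatty acid that fuels
colonocytes. `enterotyper` implements the full analysis for a
samples-by-genera abundance table plus a per-sample phenotype table
(fecal butyrate in mg/g; log10 copies/g of the two terminal
butyrate-synthesis genes, butyrate kinase *Buk* and
butyryl-CoA:acetate-CoA transferase *But*):

1. **Distance** — root Jensen–Shannon divergence between genus profiles,
   `D(p,q) = sqrt(½·KL(p‖m) + ½·KL(q‖m))`, `m = (p+q)/2`, natural log,
   so `D ∈ [0, √ln 2]` and `D` is a true metric.
2. **Clustering** — Partitioning Around Medoids (deterministic
   Kaufman–Rousseeuw BUILD+SWAP, optional seeded restarts for exact
   optimization on small inputs).
3. **Number of clusters** — prediction strength (cross-validated cluster
   stability, threshold 0.8) gates the candidates; the silhouette index
   ranks them.
4. **Ordination** — classical PCoA (Gower double-centering) of the
   distance matrix.
5. **Statistics** — per-feature Kruskal–Wallis among enterotypes with
   compact letter displays (pairwise Mann–Whitney + BH), Spearman
   co-occurrence among the predominant genera, and a Spearman ranking of
   candidate butyrate-producer genera against butyrate and the two gene
   copy variables.
6. **Simulation** — a Dirichlet-multinomial cohort generator with three
   planted enterotypes (driver genera and per-enterotype phylum totals
   seeded from a published 105-pig cohort), a latent co-occurrence
   factor, and a butyrate phenotype coupled to the producer genera and
   to *But* more strongly than *Buk*.

All user-facing functions take a data frame first and return tibbles (or
small result objects with `tidy()`/`glance()`/`autoplot()` methods), so
the pieces compose with the pipe.

## Worked example

```r
library(enterotyper)

co <- generate_cohort(default_config(seed = 1))   # 105 samples, 41 genera

ks <- choose_k(co$abundance, k_range = 2:6, n_repeats = 20, seed = 1)
ks
#> Enterotype number selection (PS threshold 0.80, 20 repeats)
#> # A tibble: 5 × 4
#>       k silhouette prediction_strength passes_threshold
#>   <int>      <dbl>               <dbl> <lgl>
#> 1     2      0.268               0.772 FALSE
#> 2     3      0.381               0.921 TRUE
#> 3     4      0.319               0.536 FALSE
#> 4     5      0.298               0.543 FALSE
#> 5     6      0.258               0.509 FALSE
#> chosen k = 3
```

Only k = 3 is stable under cross-validation (prediction strength 0.92 ≥
0.8) and it also has the best silhouette, so the cohort is stratified
into three enterotypes:

```r
fit <- pam(ks$dist, ks$chosen_k)
glance(fit)
#> # A tibble: 1 × 5
#>       k n_samples total_cost largest_cluster smallest_cluster
#> 1     3       105       25.8              41               28

adjusted_rand_index(tidy(fit), co$truth$component_labels)
#> [1] 1
```

The fitted labels agree perfectly with the planted components
(adjusted Rand index 1). Ranking the nine candidate producer genera
against fecal butyrate:

```r
rk <- phenotype_association_ranking(
  co$abundance, co$phenotype,
  c("Faecalibacterium", "Butyricicoccus", "Eubacterium hallii group",
    "Butyricimonas", "Blautia", "Anaerostipes", "Coprococcus",
    "Oscillospira", "Roseburia"))
tidy(rk)
#> # A tibble: 9 × 5
#>   taxon                    rho_butyrate p_butyrate rho_buk rho_but
#> 1 Faecalibacterium               0.889    1.21e-36  0.467   0.664
#> 2 Butyricicoccus                 0.749    4.38e-20  0.449   0.567
#> 3 Eubacterium hallii group       0.685    7.97e-16  0.312   0.648
#> ...

glance(rk)
#> # A tibble: 1 × 5
#>   rho_butyrate_buk rho_butyrate_but n_samples n_taxa_ranked n_skipped
#> 1            0.491            0.786       105             9         0
```

`Faecalibacterium` leads the ranking (rho = 0.89 with butyrate), and the
butyrate pool tracks *But* copies (rho = 0.79) more closely than *Buk*
(rho = 0.49) — the planted structure, recovered by the pipeline.

`plot_ordination(pcoa(ks$dist), fit$labels)`, `autoplot(ks)`,
`plot_cooccurrence(cooccurrence_matrix(co$abundance))` and
`autoplot(rk)` draw the standard figures. `run_simulate()`,
`run_enterotype()`, `run_association()` (or the thin CLI in
`inst/cli/enterotyper.R`) execute the same stages against files on disk,
writing TSV artifacts plus a JSON manifest that records every parameter
and seed.

## Package layout

- `R/` — implementation (io, distance, PAM, model selection, ordination,
  group statistics, simulator, pipeline, tidiers, plots)
- `tests/testthat/` — unit, property and end-to-end tests
- `vignettes/enterotyping.Rmd` — the models, conventions and design
  choices, and what the synthetic cohorts do and do not establish
- `scripts/acceptance.R` — reproduction script (above)
- `inst/cli/enterotyper.R` — command-line front end
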