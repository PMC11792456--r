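# planktonscape

Community-ecology analysis of eukaryotic plankton surveys in lakes and
reservoirs, built for the common 18S-amplicon design: a handful of sites,
a few seasons, replicated samples, and a matched panel of water-quality
measurements. The package covers the full analytical arc such studies
report:

* **Diversity** — Shannon-Wiener `H = -Σ (n_i/N) ln(n_i/N)` and Margalef
  `M = (S-1)/ln N` alpha diversity; Bray-Curtis beta diversity with NMDS
  ordination, PERMANOVA and one-way ANOVA group tests.
* **Water quality** — the Chinese trophic level index
  `TLI(Σ) = Σ W_j · TLI(j)` over Chl a, TP, TN, Secchi depth and COD_Mn,
  with weights `W_j = r_j² / Σ r²`, nutrient-status grading, and TLI
  regressions against environment and diversity.
* **Spatial structure** — haversine and environmental distance matrices,
  distance-decay regressions with Mantel-style permutation p-values, and
  per-site / per-season Mantel panels.
* **Constrained ordination** — DCA gradient-length model check, Hellinger
  RDA with Monte-Carlo (permutation) significance, overall and marginal.
* **Co-occurrence networks** — Spearman edges with BH-FDR control, Louvain
  modules, the standard topology panel (degree, density, diameter,
  clustering, path length, modularity, edge-sign split), and Zi-Pi
  key-species classification at the (2.5, 0.62) thresholds.
* **Assembly mechanisms** — the Sloan neutral community model
  `f̂_i = 1 - Beta(d; N_T m p_i, N_T m (1-p_i))` with least-squares
  migration-rate estimation and a Wilson 95% envelope, and the modified
  stochasticity ratio `MST_ij = D_ij/Ē_ij` (or `(1-D_ij)/(1-Ē_ij)` when
  `D_ij > Ē_ij`) against multinomial null communities.
* **Synthetic data** — a generator for the whole survey (OTU table,
  metadata, environment) with switchable neutral / deterministic / mixed
  assembly and known ground truth, used throughout the tests for
  parameter-recovery validation.

Everything takes and returns tibbles, composes with the pipe, and exposes
`tidy()` / `glance()` / `autoplot()` methods for fitted objects.
`run_pipeline()` drives all stages from a single config (list or YAML).

## Worked example

Simulate a survey with strong environmental filtering, score water
quality, and ask whether assembly looks deterministic:

```r
library(planktonscape)

ds <- simulate_dataset(sim_params(assembly_mode = "deterministic", seed = 42))
#> Simulated plankton survey: 2000 OTUs x 54 samples; assembly = deterministic (m = 0.1)

tli_score(ds$env, ds$metadata, by = "site")[, c("site", "tli", "status")]
#> # A tibble: 6 × 3
#>   site    tli status
#>   <chr> <dbl> <chr>
#> 1 SP1    27.6 Oligotrophic
#> 2 SP2    30.3 Mesotrophic
#> 3 SP3    33.0 Mesotrophic
#> 4 SP4    35.9 Mesotrophic
#> 5 SP5    38.4 Mesotrophic
#> 6 SP6    41.2 Mesotrophic

fit_ncm(ds$otu)
#> Sloan NCM: m = 0.1208, R^2 = 0.264 (N_T = 20000, 54 samples)
#> Partition: above = 746, below = 480, within = 681

mst(ds$otu, n_iter = 100, seed = 1)
#> MST: mean = 0.409 over 1431 pairs -> deterministic assembly

distance_decay(bray_curtis(ds$otu), haversine_matrix(ds$metadata),
               n_perm = 999, seed = 1)
#> Distance decay: slope = 0.01715, r^2 = 0.569, p = 0.001 (1431 pairs)
```

Read it bottom-up: site TLI rises along the simulated eutrophication
gradient (oligo- to mesotrophic, the span typical of a large canyon
reservoir); the neutral model fits poorly (R² = 0.26, most OTUs outside
the 95% envelope); mean MST = 0.41 < 0.5 classifies assembly as
deterministic; and community dissimilarity increases significantly with
geographic distance — all consistent with the niche-filtered truth the
generator planted. On a neutral simulation the same pipeline returns
R² ≈ 0.97, recovers the migration rate, and yields mean MST ≈ 0.8.

The same calls work on real data via `read_otu_table()`,
`read_metadata()` and `read_env()`, and `autoplot()` on any of the fitted
objects draws the standard figure for that stage.

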