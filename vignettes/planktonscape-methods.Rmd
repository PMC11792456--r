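---
title: "Methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktonscape)
```

planktonscape implements the community-ecology workflow used in amplicon
surveys of lake and reservoir plankton: diversity and ordination, trophic
level index (TLI) water-quality scoring, distance decay and Mantel
correlation, constrained ordination, co-occurrence networks with Zi-Pi
key-species detection, and assembly-mechanism inference. This vignette
documents the models behind each stage, the parameters that matter, and the
choices made where the design was genuinely open.

## Data model

All user-facing functions take plain tibbles. An OTU table is a wide tibble
(`otu_id` plus one non-negative integer column per sample); metadata carries
`sample_id`, `site`, `season`, `replicate` and coordinates; the
environmental table carries the nine measured water-quality variables with
fixed units (`Chl_a` in mg/m^3, `SD` in m, the rest in mg/L, `WT` in deg C,
`pH` unitless). Validation is strict: duplicate identifiers, negative or
fractional counts, and coordinate or log-domain violations are rejected
with the offending identifiers named, because every downstream statistic
silently degrades otherwise.

## Alpha and beta diversity

Shannon-Wiener diversity is computed in nats,
\(H = -\sum_i (n_i/N)\,\ln(n_i/N)\), and Margalef richness as
\(M = (S-1)/\ln N\). Counts, not proportions, feed both indices because the
sample size \(N\) is part of both definitions. Bray-Curtis dissimilarity
\(BC_{ij} = 1 - 2\sum_k \min(x_{ik}, x_{jk}) / (\sum_k x_{ik} + \sum_k
x_{jk})\) is computed on relative abundances by default so unequal library
sizes are not read as compositional turnover; `relative = FALSE` restores
the raw-count form. NMDS minimises Kruskal stress-1 over `n_starts` random
initialisations (vegan's monoMDS engine) and is deterministic under its
`seed`. Group differences in composition are tested by PERMANOVA
(pseudo-F, label permutation); the test behind the beta-diversity panels is
labelled in the output because several permutational tests are in common
use. Alpha-diversity and environmental group contrasts use classical
one-way ANOVA.

## Trophic level index

The TLI composite is \(\mathrm{TLI} = \sum_j W_j \,\mathrm{TLI}(j)\) over
five sub-indices (Chl a, TP, TN, SD, COD~Mn~), each of the form
\(10(a_j + b_j \ln x)\); transparency is the only decreasing sub-index.
Weights are \(W_j = r_j^2 / \sum_j r_j^2\), with the chlorophyll-correlation
vector for Chinese lakes and reservoirs, \(r = (1, 0.84, 0.82, -0.83,
0.83)\), as the default. Grading follows the standard bands: below 30
oligotrophic, 30 to below 50 mesotrophic, above 50 eutrophic with light /
middle / hyper sub-bands at 60 and 70. The published band table leaves TLI
exactly 50 unassigned (the mesotrophic band is closed at 50 from below, the
light-eutrophic band open at 50 from above); we grade it mesotrophic and
set a `boundary` flag rather than inventing a sixth band.

Surveys report one TLI per site, but the aggregation order is rarely
stated. The default here scores each sample and averages per site
(`aggregate = "sample_then_mean"`), which keeps the per-sample scores
available for regression against per-sample covariates;
`"mean_concentration"` (average the concentrations, then score) is
available because the log transform makes the two differ.

## Spatial structure

Geographic distances are great-circle (haversine, Earth radius 6371.0088
km); environmental distance is Euclidean over z-scored variables (sample
standard deviation, `scale()` convention), using all nine measured
variables unless a subset is requested. Distance decay is an OLS fit of
pairwise community dissimilarity on pairwise predictor distance over the
\(n(n-1)/2\) unique pairs. Because pairs sharing a sample are not
independent, the p-value comes from Mantel-style simultaneous row/column
permutations, not from the OLS t statistic. The similarity-decay slope is
reported as the negation of the dissimilarity slope; the two phrasings are
algebraically equivalent for similarity defined as 1 − dissimilarity.
The Mantel test itself is implemented in-package: Pearson or Spearman
correlation of the vectorised upper triangles, two-sided permutation
p-value by default (one-sided optional), with the guaranteed lower bound
\(1/(n_\mathrm{perm}+1)\). Per-site and per-season Mantel panels subset the
samples by group before testing.

## Constrained ordination

A DCA gradient-length check (vegan's decorana, axis-1 site-score range in
species-turnover SD units) chooses between linear and unimodal response
models at the conventional threshold of 3 SD. Only the decision rule is
consumed downstream, so the rescaled decorana length is used as-is. When
the linear model is indicated, RDA is fitted on Hellinger-transformed
community data (configurable to chord or none; linear ordination of raw
counts is not defensible for long-tailed abundance data) with z-scored
predictors. Axis shares are reported as percentages of the *constrained*
variance — the convention most published triplots follow — with the
constrained share of total variance reported alongside so both readings
are available. Significance uses permutation tests: overall pseudo-F, and
marginal per-variable tests by reduced-model residual permutation.

## Co-occurrence networks

Networks are built per group of samples (by default per site, seasons
pooled within site). OTUs first pass prevalence (default 1/3 of samples)
and mean-relative-abundance (default 10^-4) floors, since rank correlations
over a handful of detections are noise. All unordered pairs are then tested
with Spearman correlation; p-values use the t approximation and are
Benjamini-Hochberg adjusted across all pairs; retained edges need
\(|\rho| \ge 0.6\) and adjusted \(p < 0.05\). These thresholds are the
field's modal choice and are recorded in the network's edge attributes;
they are configurable because no standard exists.

Topology metrics follow the usual conventions: diameter and average path
length are unweighted and computed on the largest connected component;
mean local clustering counts degree-<2 nodes as 0; modularity is Newman Q
of the Louvain partition (run on the unweighted graph, deterministic under
a seed). Node roles use within-module degree \(Z_i\) (z-score of
within-module degree across the module, 0 when the module's degrees have
no spread) and among-module connectivity \(P_i = 1 - \sum_s
(k_{is}/k_i)^2\), with the (2.5, 0.62) thresholds: module hubs, network
hubs, connectors, peripherals. The published threshold definitions use
strict inequalities on both sides, leaving exact hits undefined; we assign
them to the lower category and flag them (`on_boundary`). Key species are
the non-peripheral nodes, ranked by \(P_i\) then \(Z_i\). Note that a node
whose degree is split over only two modules cannot exceed \(P_i = 0.5\);
connectors necessarily touch at least three modules.

## Assembly inference

The Sloan neutral community model predicts an OTU's occurrence frequency
from its regional mean relative abundance:
\(\hat f_i = 1 - \mathrm{Beta}(d;\, N_T m p_i,\, N_T m (1-p_i))\), with
detection limit \(d = 1/N_T\) (one read — the standard convention,
configurable). The migration rate \(m\) is estimated by least squares of
observed against predicted frequencies over OTUs, and fit quality by
\(R^2 = 1 - SSE/SST\). The 95% envelope around \(\hat f_i\) uses Wilson
score intervals at \(n = \) number of samples — smoother than
Clopper-Pearson near 0 and 1 — and partitions OTUs into above / within /
below classes.

The modified stochasticity ratio compares each pair's observed Bray-Curtis
dissimilarity \(D_{ij}\) with its null expectation \(\bar E_{ij}\):
\(\mathrm{MST}_{ij} = D_{ij}/\bar E_{ij}\) if \(D_{ij} \le \bar E_{ij}\),
else \((1-D_{ij})/(1-\bar E_{ij})\), bounded in [0, 1], with group means
above 0.5 read as stochasticity-dominated. The source literature cites the
quantity without printing a formula; the form implemented here follows the
published normalised-stochasticity-ratio framework and is echoed in the
result's metadata for auditability. The default null model redraws each
sample's library multinomially from the pooled regional relative
abundances, preserving per-sample totals and the regional abundance
distribution; a richness-preserving within-sample shuffle is available.
Pairs with degenerate null expectation (0 or 1) are excluded with a
warning.

## The synthetic-data generator

`simulate_dataset()` emulates a six-site, three-season, triplicate
reservoir survey: 54 samples, 2,000 OTUs, 20,000 reads per sample, with
sites strung along roughly 50 km of shoreline (the scale of a large canyon
reservoir). Its purpose is parameter-recovery testing, so every stochastic
ingredient has recorded ground truth.

* **Metacommunity.** Relative abundances are lognormal (`sad_mu = 0`,
  `sad_sigma = 2`), normalised — a long-tailed abundance distribution in
  the range typical of 18S surveys.
* **Neutral assembly.** Each sample's local relative abundances are drawn
  from a Dirichlet with concentration \(N_T m p\), counts multinomial at
  \(N_T\). The Dirichlet marginal is exactly the Sloan beta, so `fit_ncm()`
  recovery is a true inverse problem rather than a self-fulfilling check.
  Default `migration_rate = 0.1`.
* **Deterministic assembly.** Sampling weights are
  \(p_i \exp(-s\,(o_i - e)^2)\) with niche optima \(o_i \sim N(0,1)\) and a
  latent environmental axis \(e\) built from a site gradient (−1 to 1), a
  season offset (±0.3) and small replicate noise (sd 0.05). The default
  strength \(s = 4\) produces near-complete turnover between the gradient
  extremes and mean between-habitat Bray-Curtis around 0.6 — strong niche
  filtering, chosen once as the deterministic reference condition. `mixed`
  mode layers the Dirichlet draw on top of the filtered weights.
* **Spatial turnover.** `decay_rate` tilts each OTU's log-weight by
  `decay_rate * u_i * x_s` (loading \(u_i \sim N(0,1)\), site position
  \(x_s\) in km), producing distance decay of similarity at a controlled
  per-km rate; 0 disables it.
* **Environment.** The nine variables are generated around oligo- to
  mesotrophic reservoir baselines (e.g. SD 2.5 m, Chl a 3 mg/m^3, TP 0.02
  mg/L) with a shared latent eutrophication axis: chlorophyll and the
  nutrients increase along it, transparency decreases, water temperature
  carries the dominant season signal. TLI-vs-environment regressions on
  simulated data therefore have recoverable signs. `site_effect` and
  `season_effect` scale the respective components (0 removes them, which is
  how the ANOVA null is tested).

Everything is reproducible: a `sim_params()` object (including its seed)
yields a bit-identical dataset. Sub-seeds at fixed offsets keep the
metacommunity, environment and count draws independent of one another.

What the generator does *not* emulate: compositional dependence induced by
sequencing (counts are genuinely multinomial here), taxonomic structure
among OTUs, temporal autocorrelation beyond categorical seasons, and
detection or extraction bias. Passing recovery tests on these simulations
therefore demonstrates correctness of the estimators under their own
assumptions, not robustness to the full messiness of real amplicon data.

## Numerical choices and problem sizes

Permutation tests default to 999 permutations with mandatory seeds;
p-values use the add-one convention \((1 + \#\{\cdot\})/(1 + n_\mathrm{perm})\),
so the smallest attainable p is \(1/(n_\mathrm{perm}+1)\). The NCM
optimiser is a bounded golden-section search for \(m\) on (0, 1]. Spearman
edge p-values use the t approximation, adequate at the sample sizes where
networks are sensible and vastly cheaper than exact enumeration. The test
suite validates the stochastic machinery at the survey's own scale (54
samples, 2,000 OTUs) with 20 replicates for recovery properties, 100 null
iterations for MST, and 1,000 null simulations per permutation test for
size calibration; these sizes give Monte Carlo standard errors comfortably
inside the asserted bounds.

## Known limitations

Correlation networks on compositional data can carry spurious negative
edges; compositionally aware estimators (SparCC-style) are out of scope.
CCA is not implemented: when the DCA check recommends a unimodal model the
pipeline reports that recommendation and stops the ordination stage.
Rarefaction-based richness estimators are likewise out of scope. The
modularity values reported are Newman Q and therefore bounded by 1;
published tables occasionally print "modularity coefficients" above 1,
which cannot be standard Q and are not reproduced here.
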