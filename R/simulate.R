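#' Simulation parameters for a reservoir plankton survey
#'
#' Bundles every knob of the synthetic-data generator. Defaults emulate a
#' six-site, three-season, triplicate survey of a large canyon reservoir:
#' 54 samples, ~2,000 OTUs with a lognormal species-abundance distribution,
#' and sites strung along roughly 50 km of shoreline.
#'
#' @param n_sites,n_seasons,n_replicates Survey design (defaults 6, 3, 3).
#' @param n_otus Number of OTUs in the regional pool (default 2000).
#' @param reads_per_sample Library size per sample (default 20000).
#' @param sad_mu,sad_sigma Lognormal species-abundance parameters
#'   (defaults 0 and 2).
#' @param assembly_mode `"neutral"`, `"deterministic"`, or `"mixed"`.
#' @param migration_rate Sloan migration rate m in (0, 1] used by neutral and
#'   mixed assembly (default 0.1).
#' @param env_effect_strength Gaussian niche-filter strength for
#'   deterministic/mixed assembly (default 4; 0 disables filtering).
#' @param decay_rate Per-km rate of spatial compositional turnover in the
#'   local weights (default 0 = none).
#' @param site_effect,season_effect Multipliers on the site and season
#'   components of the environmental fields (default 1; 0 removes them).
#' @param site_coordinates Optional data frame with `site`, `latitude`,
#'   `longitude`; by default sites are spread along ~50 km of a reservoir
#'   axis near 35.9 N, 103.3 E.
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `sim_params` list.
#' @export
sim_params <- function(n_sites = 6, n_seasons = 3, n_replicates = 3,
                       n_otus = 2000, reads_per_sample = 20000,
                       sad_mu = 0, sad_sigma = 2,
                       assembly_mode = c("neutral", "deterministic", "mixed"),
                       migration_rate = 0.1, env_effect_strength = 4,
                       decay_rate = 0, site_effect = 1, season_effect = 1,
                       site_coordinates = NULL, seed = 1) {
  assembly_mode <- match.arg(assembly_mode)
  stopifnot(n_sites >= 1, n_seasons >= 1, n_replicates >= 1, n_otus >= 2,
            reads_per_sample >= 1)
  if (sad_sigma < 0) abort("sad_sigma must be >= 0.")
  if (migration_rate <= 0 || migration_rate > 1) {
    abort("migration_rate must be in (0, 1].")
  }
  if (env_effect_strength < 0) abort("env_effect_strength must be >= 0.")
  if (decay_rate < 0) abort("decay_rate must be >= 0.")
  if (assembly_mode %in% c("deterministic", "mixed") && env_effect_strength == 0) {
    abort("deterministic/mixed assembly requires env_effect_strength > 0.")
  }
  if (is.null(site_coordinates)) {
    lon <- seq(103.10, 103.60, length.out = n_sites)
    lat <- 35.88 + 0.02 * sin(seq(0, pi, length.out = n_sites))
    site_coordinates <- tibble(site = paste0("SP", seq_len(n_sites)),
                               latitude = lat, longitude = lon)
  }
  structure(list(
    n_sites = n_sites, n_seasons = n_seasons, n_replicates = n_replicates,
    n_otus = n_otus, reads_per_sample = reads_per_sample,
    sad_mu = sad_mu, sad_sigma = sad_sigma, assembly_mode = assembly_mode,
    migration_rate = migration_rate, env_effect_strength = env_effect_strength,
    decay_rate = decay_rate, site_effect = site_effect,
    season_effect = season_effect,
    site_coordinates = as_tibble(site_coordinates), seed = as.integer(seed)
  ), class = "sim_params")
}

season_names <- function(n) {
  base <- c("summer", "transition", "autumn")
  if (n <= 3) base[seq_len(n)] else c(base, paste0("season", seq_len(n - 3) + 3))
}

#' Draw a regional metacommunity abundance vector
#'
#' Relative abundances are lognormal(sad_mu, sad_sigma) normalised to sum 1,
#' giving the long-tailed species-abundance distribution typical of amplicon
#' surveys.
#'
#' @param params A [sim_params()] object.
#' @return Numeric vector `p` with `p_i > 0` and `sum(p) = 1`, named
#'   `OTU_1 ... OTU_n`.
#' @export
simulate_metacommunity <- function(params) {
  withr::with_seed(params$seed, {
    x <- rlnorm(params$n_otus, params$sad_mu, params$sad_sigma)
    p <- x / sum(x)
    names(p) <- paste0("OTU_", seq_along(p))
    p
  })
}

# Dirichlet rows via gamma draws
rdirichlet_rows <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# design table for one simulated survey (no RNG)
design_table <- function(params) {
  sites <- paste0("SP", seq_len(params$n_sites))
  seasons <- season_names(params$n_seasons)
  d <- expand.grid(replicate = seq_len(params$n_replicates),
                   season = seasons, site = sites,
                   stringsAsFactors = FALSE)
  d <- d[, c("site", "season", "replicate")]
  d$sample_id <- paste(d$site, d$season, d$replicate, sep = "_")
  coords <- params$site_coordinates
  d$latitude <- coords$latitude[match(d$site, coords$site)]
  d$longitude <- coords$longitude[match(d$site, coords$site)]
  as_tibble(d[, c("sample_id", "site", "season", "replicate",
                  "latitude", "longitude")])
}

# site positions in km along the geographic axis, centered
site_axis_km <- function(params) {
  coords <- params$site_coordinates
  ref_lat <- mean(coords$latitude)
  x <- coords$longitude * 111.3195 * cos(ref_lat * pi / 180)
  setNames(x - mean(x), coords$site)
}

# per-sample latent env axis: site gradient + season offset + replicate noise
latent_env_axis <- function(params, design) {
  site_lev <- paste0("SP", seq_len(params$n_sites))
  site_e <- params$site_effect *
    seq(-1, 1, length.out = params$n_sites)[match(design$site, site_lev)]
  seas_lev <- season_names(params$n_seasons)
  seas_off <- params$season_effect *
    seq(-0.3, 0.3, length.out = params$n_seasons)[match(design$season, seas_lev)]
  site_e + seas_off + rnorm(nrow(design), 0, 0.05)
}

# spatial turnover tilt: log-weight shift decay_rate * u_i * x_site (km)
decay_tilt <- function(params, loadings, x_km) {
  if (params$decay_rate == 0) return(rep(1, length(loadings)))
  exp(params$decay_rate * loadings * x_km)
}

counts_to_tibble <- function(counts, otu_ids, sample_ids) {
  out <- tibble(otu_id = otu_ids)
  for (j in seq_along(sample_ids)) out[[sample_ids[j]]] <- counts[, j]
  out
}

#' Simulate samples under neutral (Sloan) assembly
#'
#' Each sample's local relative abundances are drawn from a Dirichlet with
#' concentration `N_T * m * p` — the finite-sample analogue of the Sloan
#' beta marginal — and counts are then multinomial with `N_T` reads, so the
#' migration rate is recoverable by [fit_ncm()].
#'
#' @param p Metacommunity relative-abundance vector (see
#'   [simulate_metacommunity()]).
#' @param params A [sim_params()] object.
#' @return A wide OTU tibble with `n_sites * n_seasons * n_replicates`
#'   sample columns, each summing to `reads_per_sample`.
#' @export
simulate_neutral_samples <- function(p, params) {
  if (params$migration_rate <= 0) abort("migration_rate must be > 0.")
  design <- design_table(params)
  withr::with_seed(params$seed + 1L, {
    sim_neutral_impl(p, params, design)
  })
}

sim_neutral_impl <- function(p, params, design) {
  nt <- params$reads_per_sample
  x_km <- site_axis_km(params)
  loadings <- rnorm(length(p))
  counts <- matrix(0L, nrow = length(p), ncol = nrow(design))
  for (j in seq_len(nrow(design))) {
    w <- p * decay_tilt(params, loadings, x_km[design$site[j]])
    w <- w / sum(w)
    pi_j <- rdirichlet_rows(1, nt * params$migration_rate * w)[1, ]
    counts[, j] <- rmultinom(1, nt, pi_j)[, 1]
  }
  counts_to_tibble(counts, names(p), design$sample_id)
}

#' Simulate samples under deterministic (niche-filtered) assembly
#'
#' Sampling weights are `p_i * exp(-strength * (optimum_i - env_sample)^2)`,
#' renormalised, with counts multinomial at `reads_per_sample`. Replicates
#' share their site/season environmental value up to small noise, so
#' between-habitat turnover dominates within-habitat noise.
#'
#' @inheritParams simulate_neutral_samples
#' @param env Optional per-sample latent environmental axis (length =
#'   number of samples); generated from the survey design when `NULL`.
#' @return A wide OTU tibble.
#' @export
simulate_deterministic_samples <- function(p, params, env = NULL) {
  design <- design_table(params)
  withr::with_seed(params$seed + 2L, {
    sim_det_impl(p, params, design, env, dirichlet = FALSE)$otu
  })
}

sim_det_impl <- function(p, params, design, env = NULL, dirichlet = FALSE) {
  nt <- params$reads_per_sample
  s <- params$env_effect_strength
  optima <- rnorm(length(p))
  if (is.null(env)) env <- latent_env_axis(params, design)
  x_km <- site_axis_km(params)
  loadings <- rnorm(length(p))
  counts <- matrix(0L, nrow = length(p), ncol = nrow(design))
  for (j in seq_len(nrow(design))) {
    w <- p * exp(-s * (optima - env[j])^2) *
      decay_tilt(params, loadings, x_km[design$site[j]])
    w <- w / sum(w)
    if (dirichlet) {
      w <- rdirichlet_rows(1, nt * params$migration_rate * w)[1, ]
    }
    counts[, j] <- rmultinom(1, nt, w)[, 1]
  }
  list(otu = counts_to_tibble(counts, names(p), design$sample_id),
       optima = optima, env = env)
}

#' Simulate an environmental table
#'
#' Generates the nine measured water-quality variables with site and season
#' structure driven by a latent eutrophication axis: chlorophyll a and the
#' nutrients increase along it, Secchi transparency decreases, so TLI
#' regressions on synthetic data recover the expected signs.
#'
#' @param params A [sim_params()] object.
#' @param design Optional design tibble (internal use).
#' @param z Optional per-sample latent axis (internal use).
#' @return An env tibble (`sample_id`, `WT`, `pH`, `DO`, `SD`, `Chl_a`,
#'   `TN`, `TP`, `NH4_N`, `COD_Cr`, `COD_Mn`).
#' @export
simulate_env_table <- function(params, design = NULL, z = NULL) {
  if (is.null(design)) design <- design_table(params)
  withr::with_seed(params$seed + 3L, {
    sim_env_impl(params, design, z)
  })
}

sim_env_impl <- function(params, design, z = NULL) {
  n <- nrow(design)
  if (is.null(z)) z <- latent_env_axis(params, design)
  seas_lev <- season_names(params$n_seasons)
  seas_idx <- match(design$season, seas_lev)
  # seasonal forcing, strongest for water temperature
  wt_seas <- params$season_effect *
    c(6, 0, -4)[pmin(seas_idx, 3)]
  noise <- function(sdev) rnorm(n, 0, sdev)
  tibble(
    sample_id = design$sample_id,
    WT = 16 + wt_seas + 0.5 * z + noise(0.6),
    pH = 8.2 - 0.15 * params$season_effect * (seas_idx - 2) +
      0.05 * z + noise(0.05),
    DO = 8.5 - 0.4 * z - 0.1 * wt_seas + noise(0.3),
    SD = 2.5 * exp(-0.45 * z + noise(0.08)),
    Chl_a = 3.0 * exp(0.55 * z + 0.1 * params$season_effect *
                        (seas_idx == 1) + noise(0.12)),
    TN = 0.80 * exp(0.30 * z + noise(0.08)),
    TP = 0.020 * exp(0.45 * z + noise(0.10)),
    NH4_N = 0.15 * exp(0.45 * z + noise(0.10)),
    COD_Cr = 10 * exp(0.25 * z + 0.05 * params$season_effect *
                        (seas_idx - 2) + noise(0.08)),
    COD_Mn = 2.0 * exp(0.30 * z + noise(0.08))
  )
}

#' Simulate a complete survey dataset with ground truth
#'
#' Bundles an OTU table, sample metadata, environmental table and the truth
#' needed to score recovery: the metacommunity vector, the migration rate,
#' the assembly mode, per-OTU niche optima (deterministic/mixed) and the
#' latent environmental axis.
#'
#' @param params A [sim_params()] object.
#' @return A `sim_dataset` list with elements `otu`, `metadata`, `env`,
#'   `truth`, `params`.
#' @export
simulate_dataset <- function(params = sim_params()) {
  design <- design_table(params)
  p <- simulate_metacommunity(params)
  z <- withr::with_seed(params$seed + 4L, latent_env_axis(params, design))
  env <- withr::with_seed(params$seed + 3L, sim_env_impl(params, design, z))
  truth <- list(metacommunity = p, assembly_mode = params$assembly_mode,
                migration_rate = params$migration_rate, env_axis = z,
                optima = NULL)
  if (params$assembly_mode == "neutral") {
    otu <- withr::with_seed(params$seed + 1L,
                            sim_neutral_impl(p, params, design))
  } else {
    res <- withr::with_seed(params$seed + 2L,
      sim_det_impl(p, params, design, env = z,
                   dirichlet = params$assembly_mode == "mixed"))
    otu <- res$otu
    truth$optima <- res$optima
  }
  structure(list(otu = otu, metadata = design, env = env,
                 truth = truth, params = params),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated plankton survey:",
      nrow(x$otu), "OTUs x", length(otu_samples(x$otu)), "samples;",
      "assembly =", x$truth$assembly_mode,
      sprintf("(m = %.3g)\n", x$truth$migration_rate))
  invisible(x)
}
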