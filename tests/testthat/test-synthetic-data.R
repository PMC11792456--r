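test_that("metacommunity vector is a valid SAD and reproducible", {
  p <- simulate_metacommunity(sim_params(n_otus = 500, seed = 7))
  expect_equal(sum(p), 1)
  expect_true(all(p > 0))
  expect_equal(p, simulate_metacommunity(sim_params(n_otus = 500, seed = 7)))

  # sigma = 0 collapses to the uniform metacommunity
  p2 <- simulate_metacommunity(sim_params(n_otus = 2, sad_sigma = 0))
  expect_equal(as.numeric(p2), c(0.5, 0.5))

  # long tail: log rank-abundance curve bends downward (concave in
  # log-log space, unlike a straight power law)
  p3 <- sort(simulate_metacommunity(sim_params(n_otus = 1000, sad_sigma = 2,
                                               seed = 1)), decreasing = TRUE)
  lr <- log(seq_along(p3))
  quad <- lm(log(p3) ~ lr + I(lr^2))
  expect_lt(coef(quad)[["I(lr^2)"]], 0)
})

test_that("parameter validation rejects degenerate settings", {
  expect_error(sim_params(sad_sigma = -1), "sad_sigma")
  expect_error(sim_params(migration_rate = 0), "migration_rate")
  expect_error(sim_params(migration_rate = 1.5), "migration_rate")
  expect_error(sim_params(assembly_mode = "deterministic",
                          env_effect_strength = 0), "env_effect_strength")
})

test_that("neutral samples have exact library sizes and are seed-stable", {
  pr <- sim_params(n_otus = 200, reads_per_sample = 1000, seed = 5)
  p <- simulate_metacommunity(pr)
  otu <- simulate_neutral_samples(p, pr)
  m <- otu_counts(otu)
  expect_true(all(colSums(m) == 1000))
  expect_equal(ncol(m), 54)
  expect_identical(otu, simulate_neutral_samples(p, pr))
})

test_that("with full migration the mean local composition approaches p", {
  pr <- sim_params(n_otus = 50, n_sites = 10, n_replicates = 4,
                   reads_per_sample = 5000, migration_rate = 1, seed = 2)
  p <- simulate_metacommunity(pr)
  otu <- simulate_neutral_samples(p, pr)  # 120 samples
  m <- otu_counts(otu)
  rel <- sweep(m, 2, colSums(m), "/")
  est <- rowMeans(rel)
  # per-OTU tolerance ~ 5 standard errors of the mean local abundance
  se <- sqrt(p * (1 - p) / (5000 * 1 + 1) / ncol(m)) + 1e-5
  expect_true(all(abs(est - p) < 5 * se + 0.2 * p))
})

test_that("deterministic assembly separates opposite environments", {
  pr <- sim_params(n_otus = 300, n_sites = 2, n_seasons = 1,
                   n_replicates = 5, reads_per_sample = 5000,
                   assembly_mode = "deterministic", seed = 9)
  p <- simulate_metacommunity(pr)
  env <- rep(c(-1.5, 1.5), each = 5)
  otu <- simulate_deterministic_samples(p, pr, env = env)
  d <- as.matrix(bray_curtis(otu))
  within <- c(d[1:5, 1:5][upper.tri(d[1:5, 1:5])],
              d[6:10, 6:10][upper.tri(d[6:10, 6:10])])
  between <- d[1:5, 6:10]
  expect_gt(mean(between), mean(within))
  expect_identical(otu, simulate_deterministic_samples(p, pr, env = env))
})

test_that("zero filtering strength reduces deterministic weights to p", {
  pr <- sim_params(n_otus = 100, n_sites = 2, n_seasons = 1,
                   n_replicates = 2, reads_per_sample = 200000, seed = 4,
                   env_effect_strength = 0)
  p <- simulate_metacommunity(pr)
  otu <- simulate_deterministic_samples(p, pr)
  rel <- rowMeans(otu_counts(otu)) / 200000
  expect_lt(max(abs(rel - p)), 0.01)
})

test_that("simulated datasets carry truth and the 6x3x3 default design", {
  ds <- simulate_dataset(sim_params(n_otus = 100, reads_per_sample = 500))
  expect_equal(nrow(ds$metadata), 54)
  expect_equal(length(otu_samples(ds$otu)), 54)
  expect_setequal(ds$metadata$sample_id, ds$env$sample_id)
  expect_equal(ds$truth$assembly_mode, "neutral")
  expect_equal(ds$truth$migration_rate, 0.1)
  expect_equal(sum(ds$truth$metacommunity), 1)

  ds2 <- simulate_dataset(sim_params(n_otus = 100, reads_per_sample = 500))
  expect_identical(ds$otu, ds2$otu)
  expect_identical(ds$env, ds2$env)
})

test_that("environment couples to the eutrophication axis with known signs", {
  # TLI regressed on TP recovers a positive slope, on SD a negative slope,
  # in nearly all simulated datasets
  signs <- vapply(1:25, function(s) {
    env <- simulate_env_table(sim_params(seed = s))
    tl <- tli_score(env, by = "sample")
    reg <- tli_regressions(tl$tli, env[, c("TP", "SD", "NH4_N")])
    c(reg$slope[reg$predictor == "TP"] > 0,
      reg$slope[reg$predictor == "SD"] < 0,
      reg$slope[reg$predictor == "NH4_N"] > 0)
  }, logical(3))
  expect_gte(mean(signs[1, ]), 0.95)
  expect_gte(mean(signs[2, ]), 0.95)
  expect_gte(mean(signs[3, ]), 0.95)
})

test_that("removing the season effect removes the WT season signal", {
  pvals <- vapply(1:40, function(s) {
    pr <- sim_params(season_effect = 0, seed = s)
    env <- simulate_env_table(pr)
    md <- simulate_dataset(sim_params(n_otus = 10, reads_per_sample = 50,
                                      seed = s))$metadata
    one_way_anova(env$WT, md$season[match(env$sample_id, md$sample_id)])$p_value
  }, numeric(1))
  # p should look uniform: no excess of small values
  expect_lt(mean(pvals < 0.05), 0.2)
  expect_gt(mean(pvals), 0.3)

  # and with the effect on, the signal is unmistakable
  env <- simulate_env_table(sim_params(seed = 1))
  md <- simulate_dataset(sim_params(n_otus = 10, reads_per_sample = 50,
                                    seed = 1))$metadata
  p_on <- one_way_anova(env$WT, md$season[match(env$sample_id,
                                                md$sample_id)])$p_value
  expect_lt(p_on, 1e-6)
})
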