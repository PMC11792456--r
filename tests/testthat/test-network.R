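test_that("OTU filtering matches a brute-force recount", {
  set.seed(14)
  m <- matrix(rbinom(30 * 9, 1, 0.4) * rpois(270, 20), nrow = 30)
  m[1, ] <- c(5, rep(0, 8))       # present in 1 of 9
  otu <- toy_otu(m)
  kept <- filter_otus_for_network(otu, min_prevalence = 1/3,
                                  min_mean_abund = 0)
  rel <- sweep(m, 2, colSums(m), "/")
  expect_equal(nrow(kept), sum(rowMeans(m > 0) >= 1/3))
  expect_false("OTU_1" %in% kept$otu_id)

  ident <- filter_otus_for_network(otu, 0, 0)
  expect_equal(ident, otu)
  expect_error(filter_otus_for_network(otu, 1.5, 0), "0, 1")
  expect_error(filter_otus_for_network(otu, 1, 0.99), "No OTUs")
})

test_that("correlation edges catch perfect, inverse and null structure", {
  set.seed(15)
  base <- rpois(10, 50) + 1
  m <- rbind(base, base * 2, max(base) + 1 - base,
             matrix(rpois(50, 30), nrow = 5))
  otu <- toy_otu(m)
  edges <- correlation_edges(otu, min_abs_r = 0.95, alpha = 0.05)
  pos <- edges[edges$otu_1 == "OTU_1" & edges$otu_2 == "OTU_2", ]
  expect_equal(pos$rho, 1)
  expect_equal(pos$sign, "positive")
  neg <- edges[edges$otu_1 %in% c("OTU_1", "OTU_3") &
                 edges$otu_2 %in% c("OTU_3", "OTU_1"), ]
  expect_equal(neg$rho, -1)
  expect_equal(neg$sign, "negative")

  const <- toy_otu(rbind(rep(3, 10), m[1:2, ]))
  expect_warning(correlation_edges(const, min_abs_r = 0.9), "constant")
  expect_error(correlation_edges(toy_otu(matrix(1:8, 2))), "5 samples")
})

test_that("BH adjustment keeps the null edge fraction near the FDR", {
  set.seed(16)
  m <- matrix(rpois(60 * 20, 20), nrow = 60)  # independent OTUs
  edges <- correlation_edges(toy_otu(m), min_abs_r = 0, alpha = 0.05)
  expect_lte(nrow(edges) / choose(60, 2), 0.05)
})

test_that("topology metrics match hand enumeration on canonical graphs", {
  # complete graph K4
  k4 <- build_co_network(tibble::tibble(
    otu_1 = c("a", "a", "a", "b", "b", "c"),
    otu_2 = c("b", "c", "d", "c", "d", "d"),
    rho = rep(0.9, 6), p_adjusted = rep(0.001, 6), sign = rep("positive", 6)))
  tm <- topology_metrics(k4)
  expect_equal(tm$density, 1)
  expect_equal(tm$average_clustering, 1)
  expect_equal(tm$diameter, 1)
  expect_equal(tm$average_path_length, 1)
  expect_equal(tm$pct_positive, 100)

  # path graph a-b-c
  path <- build_co_network(tibble::tibble(
    otu_1 = c("a", "b"), otu_2 = c("b", "c"), rho = c(0.8, -0.7),
    p_adjusted = c(0.01, 0.01), sign = c("positive", "negative")))
  tp <- topology_metrics(path)
  expect_equal(tp$average_degree, 4 / 3)
  expect_equal(tp$diameter, 2)
  expect_equal(tp$average_path_length, (1 + 1 + 2) / 3)
  expect_equal(tp$pct_positive + tp$pct_negative, 100)
})

test_that("module detection recovers planted partitions", {
  # two disjoint 4-cliques
  cl <- function(nodes) {
    pr <- utils::combn(nodes, 2)
    tibble::tibble(otu_1 = pr[1, ], otu_2 = pr[2, ], rho = 0.9,
                   p_adjusted = 0.001, sign = "positive")
  }
  g <- build_co_network(dplyr::bind_rows(cl(paste0("a", 1:4)),
                                         cl(paste0("b", 1:4))))
  memb <- detect_modules(g, seed = 1)
  expect_equal(length(unique(memb)), 2)
  expect_equal(length(unique(memb[paste0("a", 1:4)])), 1)
  expect_equal(length(unique(memb[paste0("b", 1:4)])), 1)

  # explicit Q of the 2-block partition: 2 * (6/12 - (16/24)^2 / ... )
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  q_brute <- topology_brute(adj, membership = memb[rownames(adj)])$modularity
  expect_equal(topology_metrics(g, seed = 1)$modularity, q_brute)
  expect_equal(q_brute, 0.5)

  # complete graph -> one module, Q >= 0 bound
  k4 <- build_co_network(cl(letters[1:4]))
  m4 <- detect_modules(k4, seed = 1)
  expect_equal(length(unique(m4)), 1)
  expect_gte(igraph::modularity(k4, m4), 0)
})

test_that("Zi-Pi formulas hit their closed-form cases and role map", {
  # node with degree 4 split evenly over 2 modules: Pi = 1 - 2 * 0.25 = 0.5
  edges <- tibble::tibble(
    otu_1 = c("hub", "hub", "hub", "hub", "m1a", "m2a"),
    otu_2 = c("m1a", "m1b", "m2a", "m2b", "m1b", "m2b"),
    rho = 0.9, p_adjusted = 0.001, sign = "positive")
  g <- build_co_network(edges)
  part <- c(hub = 1, m1a = 1, m1b = 1, m2a = 2, m2b = 2)
  roles <- zi_pi(g, part)
  expect_equal(roles$pi[roles$otu_id == "hub"], 0.5)
  # all-internal node: Pi = 0 (m1a touches only module-1 nodes)
  expect_equal(roles$pi[roles$otu_id == "m1a"], 0)
  # mean Zi within each module ~ 0
  for (mm in unique(roles$module)) {
    zz <- roles$zi[roles$module == mm]
    if (sd(zz) > 0) expect_lt(abs(mean(zz)), 1e-12)
  }
  expect_true(all(roles$pi >= 0 & roles$pi < 1))
  expect_error(zi_pi(g, part[-1]), "cover")
})

test_that("role thresholds classify the (Zi, Pi) plane as published", {
  grid <- tibble::tibble(zi = c(3.0, 3.0, 1.0, 1.0, 2.5, 1.0),
                         pi = c(0.7, 0.5, 0.7, 0.5, 0.62, 0.62))
  role <- dplyr::case_when(
    grid$zi > 2.5 & grid$pi > 0.62 ~ "network hub",
    grid$zi > 2.5 ~ "module hub",
    grid$pi > 0.62 ~ "connector",
    TRUE ~ "peripheral")
  expect_equal(role, c("network hub", "module hub", "connector",
                       "peripheral", "peripheral", "peripheral"))
})

test_that("key species are exactly the non-peripheral nodes, ranked", {
  # planted connector: one node bridging two cliques
  cl <- function(nodes) {
    pr <- utils::combn(nodes, 2)
    tibble::tibble(otu_1 = pr[1, ], otu_2 = pr[2, ], rho = 0.9,
                   p_adjusted = 0.001, sign = "positive")
  }
  # spanning three modules evenly gives Pi = 1 - 3*(1/3)^2 = 2/3 > 0.62
  edges <- dplyr::bind_rows(
    cl(paste0("a", 1:5)), cl(paste0("b", 1:5)), cl(paste0("c", 1:5)),
    tibble::tibble(otu_1 = "bridge",
                   otu_2 = c("a1", "a2", "b1", "b2", "c1", "c2"),
                   rho = 0.9, p_adjusted = 0.001, sign = "positive"))
  g <- build_co_network(edges)
  memb <- detect_modules(g, seed = 2)
  roles <- zi_pi(g, memb)
  ks <- key_species(roles)
  expect_equal(nrow(ks), sum(roles$role != "peripheral"))
  expect_true("bridge" %in% ks$otu_id)
  expect_equal(roles$role[roles$otu_id == "bridge"], "connector")
  expect_true(all(diff(ks$pi) <= 1e-12 | diff(ks$zi) <= 0))

  # all-peripheral network -> empty key-species list
  k3 <- build_co_network(cl(c("x", "y", "z")))
  r3 <- zi_pi(k3, detect_modules(k3, seed = 1))
  expect_equal(nrow(key_species(r3)), 0)
})

test_that("per-site networks are built over each site's samples only", {
  ds <- simulate_dataset(sim_params(n_otus = 100, reads_per_sample = 2000,
                                    n_sites = 2, assembly_mode = "deterministic",
                                    seed = 17))
  nets <- co_occurrence_networks(ds$otu, ds$metadata, by = "site",
                                 min_abs_r = 0.7)
  expect_setequal(names(nets), c("SP1", "SP2"))
  expect_true(all(vapply(nets, igraph::ecount, numeric(1)) > 0))
  for (g in nets) {
    expect_true(all(abs(igraph::E(g)$rho) >= 0.7))
    expect_true(all(igraph::E(g)$p_adjusted < 0.05))
    expect_equal(igraph::count_multiple(g), rep(1, igraph::ecount(g)))
  }
})
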