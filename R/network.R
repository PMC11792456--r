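#' Filter OTUs before network construction
#'
#' Pairwise correlations over few samples are unstable for rare OTUs, so
#' networks are built from OTUs passing prevalence and mean-relative-
#' abundance floors.
#'
#' @param otu Wide OTU tibble.
#' @param min_prevalence Minimum fraction of samples with a non-zero count
#'   (default 1/3).
#' @param min_mean_abund Minimum mean relative abundance (default 1e-4).
#' @return The filtered OTU tibble.
#' @export
filter_otus_for_network <- function(otu, min_prevalence = 1/3,
                                    min_mean_abund = 1e-4) {
  if (min_prevalence < 0 || min_prevalence > 1 ||
      min_mean_abund < 0 || min_mean_abund > 1) {
    abort("Thresholds must lie in [0, 1].")
  }
  m <- otu_counts(otu)
  rel <- sweep(m, 2, colSums(m), "/")
  keep <- rowMeans(m > 0) >= min_prevalence &
    rowMeans(rel) >= min_mean_abund
  if (!any(keep)) {
    abort("No OTUs survive the filters; lower min_prevalence/min_mean_abund.")
  }
  otu[keep, ]
}

#' Significant pairwise correlations between OTUs
#'
#' Tests every unordered OTU pair (Spearman by default) across samples,
#' adjusts p-values by Benjamini-Hochberg over all pairs, and retains pairs
#' with `|rho| >= min_abs_r` and adjusted `p < alpha`. Constant OTU vectors
#' are skipped with a warning.
#'
#' @param otu Wide OTU tibble (typically after [filter_otus_for_network()]).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param min_abs_r Correlation-magnitude floor (default 0.6).
#' @param alpha Adjusted-p ceiling (default 0.05).
#' @return A tibble of retained edges: `otu_1`, `otu_2`, `rho`, `p_value`,
#'   `p_adjusted`, `sign`.
#' @export
correlation_edges <- function(otu, method = c("spearman", "pearson"),
                              min_abs_r = 0.6, alpha = 0.05) {
  method <- match.arg(method)
  m <- otu_counts(otu)
  if (ncol(m) < 5) abort("Need at least 5 samples for pairwise correlations.")
  const <- apply(m, 1, sd) == 0
  if (any(const)) {
    warn(paste0("Skipping constant OTU(s): ",
                paste(head(rownames(m)[const], 5), collapse = ", ")))
    m <- m[!const, , drop = FALSE]
  }
  if (nrow(m) < 2) abort("Fewer than 2 variable OTUs; no pairs to test.")
  x <- t(m)
  rho <- cor(x, method = method)
  n <- nrow(x)
  # t approximation for the correlation p-value (two-sided)
  r <- rho[upper.tri(rho)]
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  idx <- which(upper.tri(rho), arr.ind = TRUE)
  edges <- tibble(otu_1 = rownames(rho)[idx[, 1]],
                  otu_2 = rownames(rho)[idx[, 2]],
                  rho = r, p_value = p,
                  p_adjusted = p.adjust(p, method = "BH"))
  edges <- edges %>%
    filter(abs(.data$rho) >= min_abs_r, .data$p_adjusted < alpha) %>%
    mutate(sign = ifelse(.data$rho >= 0, "positive", "negative"))
  edges
}

#' Build an igraph co-occurrence network from an edge table
#'
#' @param edges Edge tibble from [correlation_edges()].
#' @param otu Optional OTU tibble; when given, nodes carry a mean
#'   relative-abundance attribute and isolated filtered OTUs are excluded.
#' @return An undirected simple igraph with edge attributes `rho`,
#'   `p_adjusted`, `sign` and node attribute `abundance` (if `otu` given).
#' @export
build_co_network <- function(edges, otu = NULL) {
  g <- igraph::graph_from_data_frame(
    edges[, c("otu_1", "otu_2", "rho", "p_adjusted", "sign")],
    directed = FALSE)
  if (!is.null(otu)) {
    m <- otu_counts(otu)
    rel <- rowMeans(sweep(m, 2, colSums(m), "/"))
    igraph::V(g)$abundance <- as.numeric(rel[igraph::V(g)$name])
  }
  g
}

#' Co-occurrence network per group of samples
#'
#' Convenience wrapper running the filter -> correlate -> build chain within
#' each level of a metadata column (typically one network per site).
#'
#' @param otu Wide OTU tibble.
#' @param metadata Sample metadata.
#' @param by Grouping column (default `"site"`).
#' @param ... Passed to [correlation_edges()].
#' @param min_prevalence,min_mean_abund Passed to
#'   [filter_otus_for_network()].
#' @return Named list of igraph objects, one per group.
#' @export
co_occurrence_networks <- function(otu, metadata, by = "site",
                                   min_prevalence = 1/3,
                                   min_mean_abund = 1e-4, ...) {
  metadata <- validate_metadata(metadata, otu)
  groups <- split(metadata$sample_id, metadata[[by]])
  lapply(groups, function(ids) {
    sub <- otu[, c("otu_id", intersect(otu_samples(otu), ids))]
    sub <- filter_otus_for_network(sub, min_prevalence, min_mean_abund)
    edges <- correlation_edges(sub, ...)
    build_co_network(edges, sub)
  })
}

#' Topology panel of a co-occurrence network
#'
#' Node/edge counts, average degree, density, diameter and average path
#' length (unweighted, over the largest connected component), mean local
#' clustering (degree-<2 nodes contribute 0), Newman modularity of the
#' [detect_modules()] partition, and the positive/negative edge split.
#'
#' @param network An igraph co-occurrence network.
#' @param seed Seed for module detection (default 1).
#' @return A one-row tibble with the metric columns.
#' @export
topology_metrics <- function(network, seed = 1) {
  nn <- igraph::vcount(network)
  ne <- igraph::ecount(network)
  if (nn == 0) abort("Empty network.")
  if (ne == 0) {
    return(tibble(n_nodes = nn, n_edges = 0, average_degree = 0,
                  diameter = NA_real_, density = 0, modularity = NA_real_,
                  average_clustering = 0, average_path_length = NA_real_,
                  pct_positive = NA_real_, pct_negative = NA_real_))
  }
  comp <- igraph::components(network)
  giant <- igraph::induced_subgraph(
    network, which(comp$membership == which.max(comp$csize)))
  memb <- detect_modules(network, seed = seed)
  q <- igraph::modularity(network, memb[igraph::V(network)$name])
  cl <- igraph::transitivity(network, type = "localundirected", isolates = "zero")
  cl[is.na(cl)] <- 0
  sgn <- if ("sign" %in% igraph::edge_attr_names(network)) {
    igraph::E(network)$sign
  } else {
    rep("positive", ne)
  }
  tibble(
    n_nodes = nn, n_edges = ne,
    average_degree = 2 * ne / nn,
    diameter = igraph::diameter(giant, weights = NA),
    density = 2 * ne / (nn * (nn - 1)),
    modularity = q,
    average_clustering = mean(cl),
    average_path_length = igraph::mean_distance(giant, weights = NA),
    pct_positive = 100 * mean(sgn == "positive"),
    pct_negative = 100 * mean(sgn == "negative")
  )
}

#' Detect network modules
#'
#' Louvain modularity maximisation on the unweighted graph (signs and
#' correlation magnitudes are kept as edge attributes but do not steer the
#' partition). Deterministic under the seed; isolated nodes become their own
#' modules.
#'
#' @param network An igraph object.
#' @param seed Integer seed.
#' @return Named integer vector: node name -> module id.
#' @export
detect_modules <- function(network, seed = 1) {
  if (igraph::vcount(network) == 0) abort("Empty network.")
  if (igraph::ecount(network) == 0) {
    return(setNames(seq_len(igraph::vcount(network)), igraph::V(network)$name))
  }
  cl <- withr::with_seed(seed,
    igraph::cluster_louvain(network, weights = NA))
  setNames(igraph::membership(cl), igraph::V(network)$name)
}

#' Within-module degree (Zi) and among-module connectivity (Pi)
#'
#' `Zi = (k_im - mean(k_m)) / sd(k_m)` over the nodes of the node's module
#' (0 when the module's degrees have zero spread); `Pi = 1 - sum_s
#' (k_is / k_i)^2` over modules s. Roles follow the (2.5, 0.62) thresholds:
#' module hub (Zi > 2.5, Pi < 0.62), network hub (Zi > 2.5, Pi > 0.62),
#' connector (Zi < 2.5, Pi > 0.62), else peripheral. Exact threshold hits
#' fall to the lower category and are flagged.
#'
#' @param network An igraph object.
#' @param partition Named membership vector from [detect_modules()].
#' @return A tibble: `otu_id`, `module`, `degree`, `zi`, `pi`, `role`,
#'   `on_boundary`.
#' @export
zi_pi <- function(network, partition) {
  nodes <- igraph::V(network)$name
  if (!all(nodes %in% names(partition))) {
    abort("Partition does not cover all nodes.")
  }
  memb <- partition[nodes]
  adj <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  adj <- (adj > 0) * 1
  k <- rowSums(adj)
  # per-node links into each module
  mods <- sort(unique(memb))
  k_to_mod <- vapply(mods, function(mm) {
    rowSums(adj[, memb == mm, drop = FALSE])
  }, numeric(length(nodes)))
  if (is.null(dim(k_to_mod))) k_to_mod <- matrix(k_to_mod, nrow = length(nodes))
  own <- match(memb, mods)
  k_in <- k_to_mod[cbind(seq_along(nodes), own)]
  zi <- numeric(length(nodes))
  for (mm in seq_along(mods)) {
    in_mod <- own == mm
    mu <- mean(k_in[in_mod])
    sg <- sd(k_in[in_mod])
    zi[in_mod] <- if (is.na(sg) || sg == 0) 0 else (k_in[in_mod] - mu) / sg
  }
  pi_v <- ifelse(k == 0, 0, 1 - rowSums((k_to_mod / pmax(k, 1))^2))
  role <- dplyr::case_when(
    zi > 2.5 & pi_v > 0.62 ~ "network hub",
    zi > 2.5 ~ "module hub",
    pi_v > 0.62 ~ "connector",
    TRUE ~ "peripheral"
  )
  tibble(otu_id = nodes, module = as.integer(memb),
         degree = as.numeric(unname(k)),
         zi = unname(zi), pi = unname(pi_v), role = role,
         on_boundary = zi == 2.5 | pi_v == 0.62)
}

#' Key species of a co-occurrence network
#'
#' Connectors, module hubs and network hubs — the non-peripheral Zi-Pi
#' roles — ranked by Pi then Zi, annotated with mean relative abundance and
#' (optionally) taxonomy.
#'
#' @param roles Output of [zi_pi()].
#' @param otu Optional OTU tibble for abundance annotation.
#' @param taxonomy Optional taxonomy tibble.
#' @return Tibble of key nodes (possibly empty), ranked.
#' @export
key_species <- function(roles, otu = NULL, taxonomy = NULL) {
  out <- roles %>% filter(.data$role != "peripheral") %>%
    arrange(desc(.data$pi), desc(.data$zi))
  if (!is.null(otu)) {
    m <- otu_counts(otu)
    rel <- rowMeans(sweep(m, 2, colSums(m), "/"))
    out$mean_rel_abundance <- as.numeric(rel[out$otu_id])
  }
  if (!is.null(taxonomy)) {
    out <- left_join(out, as_tibble(taxonomy), by = "otu_id")
  }
  out
}

#' Zi-Pi scatter of node roles
#'
#' @param roles Output of [zi_pi()].
#' @return A ggplot object with the (2.5, 0.62) threshold lines.
#' @export
plot_zi_pi <- function(roles) {
  ggplot2::ggplot(roles, ggplot2::aes(x = .data$pi, y = .data$zi,
                                      colour = .data$role)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 2.5, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0.62, linetype = "dashed") +
    ggplot2::labs(x = "Among-module connectivity (Pi)",
                  y = "Within-module degree (Zi)", colour = NULL) +
    ggplot2::theme_minimal()
}
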