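# Small in-code fixtures and independent brute-force oracles shared by the
# unit tests. Oracles use only base R and explicit enumeration, independent
# of the package code paths they check.

toy_otu <- function(counts, otu_ids = NULL, sample_ids = NULL) {
  counts <- as.matrix(counts)
  if (is.null(otu_ids)) otu_ids <- paste0("OTU_", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(counts)))
  out <- tibble::tibble(otu_id = otu_ids)
  for (j in seq_along(sample_ids)) out[[sample_ids[j]]] <- counts[, j]
  out
}

toy_metadata <- function(n_sites = 3, n_seasons = 1, n_reps = 2) {
  d <- expand.grid(replicate = seq_len(n_reps),
                   season = c("summer", "transition", "autumn")[seq_len(n_seasons)],
                   site = paste0("SP", seq_len(n_sites)),
                   stringsAsFactors = FALSE)
  tibble::tibble(
    sample_id = paste(d$site, d$season, d$replicate, sep = "_"),
    site = d$site, season = d$season, replicate = d$replicate,
    latitude = 35.9 + 0.01 * as.integer(factor(d$site)),
    longitude = 103.2 + 0.05 * as.integer(factor(d$site)))
}

# ---- brute-force oracles -------------------------------------------------

bc_brute <- function(x, y) {
  1 - 2 * sum(pmin(x, y)) / (sum(x) + sum(y))
}

# all-pairs shortest paths by BFS on an adjacency matrix (unweighted)
bfs_dist_brute <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    frontier <- s
    lvl <- 0
    while (length(frontier) > 0) {
      lvl <- lvl + 1
      nxt <- integer(0)
      for (v in frontier) {
        for (w in which(adj[v, ] > 0)) {
          if (d[s, w] > lvl) { d[s, w] <- lvl; nxt <- c(nxt, w) }
        }
      }
      frontier <- unique(nxt)
    }
  }
  d
}

# topology metrics by explicit enumeration; path metrics on largest component
topology_brute <- function(adj, signs = NULL, membership = NULL) {
  n <- nrow(adj)
  e <- sum(adj[upper.tri(adj)] > 0)
  deg <- rowSums(adj > 0)
  # local clustering by triangle counting
  cl <- vapply(seq_len(n), function(v) {
    nb <- which(adj[v, ] > 0)
    if (length(nb) < 2) return(0)
    pairs <- utils::combn(nb, 2)
    tri <- sum(adj[t(pairs)] > 0)
    tri / ncol(pairs)
  }, numeric(1))
  d <- bfs_dist_brute(adj)
  comp_id <- rep(NA_integer_, n)
  cid <- 0
  for (v in seq_len(n)) {
    if (is.na(comp_id[v])) {
      cid <- cid + 1
      comp_id[is.finite(d[v, ])] <- cid
    }
  }
  giant <- which(comp_id == which.max(tabulate(comp_id)))
  dg <- d[giant, giant, drop = FALSE]
  finite_off <- dg[upper.tri(dg)]
  out <- list(
    n_nodes = n, n_edges = e, average_degree = 2 * e / n,
    density = 2 * e / (n * (n - 1)),
    average_clustering = mean(cl),
    diameter = if (length(finite_off) > 0) max(finite_off) else NA_real_,
    average_path_length = if (length(finite_off) > 0) mean(finite_off) else NA_real_)
  if (!is.null(signs)) {
    out$pct_positive <- 100 * mean(signs == "positive")
    out$pct_negative <- 100 * mean(signs == "negative")
  }
  if (!is.null(membership)) {
    # Newman Q = sum over pairs in same module of (A_ij - k_i k_j / 2m) / 2m
    m2 <- 2 * e
    q <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + (adj[i, j] > 0) - deg[i] * deg[j] / m2
      }
    }
    out$modularity <- as.numeric(q / m2)
  }
  out
}

# Zi/Pi by direct loops over nodes and modules
zi_pi_brute <- function(adj, membership) {
  n <- nrow(adj)
  k <- rowSums(adj > 0)
  mods <- sort(unique(membership))
  k_in <- vapply(seq_len(n), function(v) {
    sum(adj[v, membership == membership[v]] > 0)
  }, numeric(1))
  zi <- numeric(n)
  for (mm in mods) {
    idx <- which(membership == mm)
    sg <- stats::sd(k_in[idx])
    zi[idx] <- if (is.na(sg) || sg == 0) 0 else
      (k_in[idx] - mean(k_in[idx])) / sg
  }
  pi_v <- vapply(seq_len(n), function(v) {
    if (k[v] == 0) return(0)
    1 - sum(vapply(mods, function(mm) {
      (sum(adj[v, membership == mm] > 0) / k[v])^2
    }, numeric(1)))
  }, numeric(1))
  list(zi = zi, pi = pi_v)
}

# random Erdos-Renyi-ish co-occurrence graph as an edge tibble
random_graph_edges <- function(n_nodes, p_edge = 0.15) {
  nodes <- paste0("OTU_", seq_len(n_nodes))
  pairs <- utils::combn(n_nodes, 2)
  keep <- stats::runif(ncol(pairs)) < p_edge
  pairs <- pairs[, keep, drop = FALSE]
  rho <- stats::runif(ncol(pairs), -1, 1)
  tibble::tibble(otu_1 = nodes[pairs[1, ]], otu_2 = nodes[pairs[2, ]],
                 rho = rho, p_adjusted = stats::runif(ncol(pairs), 0, 0.05),
                 sign = ifelse(rho >= 0, "positive", "negative"))
}
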