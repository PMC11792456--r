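#' Shannon-Wiener diversity index
#'
#' `H = -sum((n_i/N) * ln(n_i/N))` over taxa with non-zero counts, in nats.
#'
#' @param counts Non-negative numeric vector of counts for one sample.
#' @return The index value (`0 <= H <= ln(S)`).
#' @export
shannon_index <- function(counts) {
  if (any(counts < 0)) abort("Counts must be non-negative.")
  n <- sum(counts)
  if (n <= 0) abort("Shannon index undefined for an all-zero sample.")
  p <- counts[counts > 0] / n
  -sum(p * log(p))
}

#' Margalef richness index
#'
#' `M = (S - 1) / ln(N)` where S is the number of taxa observed and N the
#' total number of individuals.
#'
#' @param counts Non-negative numeric vector of counts for one sample.
#' @return The index value (`M >= 0`).
#' @export
margalef_index <- function(counts) {
  if (any(counts < 0)) abort("Counts must be non-negative.")
  n <- sum(counts)
  if (n < 2) abort("Margalef index requires at least 2 individuals (ln N domain).")
  s <- sum(counts > 0)
  (s - 1) / log(n)
}

#' Per-sample alpha diversity table
#'
#' @param otu Wide OTU tibble.
#' @return A tibble with `sample_id`, `shannon` (H, nats), `margalef` (M),
#'   `richness` (S, observed OTUs), `reads` (N).
#' @export
alpha_diversity <- function(otu) {
  m <- otu_counts(otu)
  purrr::map_dfr(colnames(m), function(s) {
    x <- m[, s]
    tibble(sample_id = s, shannon = shannon_index(x),
           margalef = margalef_index(x), richness = sum(x > 0),
           reads = sum(x))
  })
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC_ij = 1 - 2 * sum_k min(x_ik, x_jk) / (sum_k x_ik + sum_k x_jk)`.
#' By default samples are first scaled to relative abundances so unequal
#' library sizes do not masquerade as compositional difference.
#'
#' @param otu Wide OTU tibble.
#' @param relative Scale samples to proportions first (default `TRUE`).
#' @return A [stats::dist] object labelled by sample id.
#' @export
bray_curtis <- function(otu, relative = TRUE) {
  m <- otu_counts(otu)
  if (any(colSums(m) == 0)) {
    abort(paste0("Sample(s) with zero total: ",
                 paste(colnames(m)[colSums(m) == 0], collapse = ", ")))
  }
  if (relative) m <- sweep(m, 2, colSums(m), "/")
  vegan::vegdist(t(m), method = "bray")
}

#' Pairwise distances as a tidy tibble
#'
#' @param d A [stats::dist] object or symmetric labelled matrix.
#' @param value Name for the value column (default `"distance"`).
#' @return Tibble of unique unordered pairs: `sample_1`, `sample_2`, value.
#' @export
dist_pairs <- function(d, value = "distance") {
  m <- as.matrix(d)
  labs <- rownames(m)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(m)))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  out <- tibble(sample_1 = labs[idx[, 1]], sample_2 = labs[idx[, 2]])
  out[[value]] <- m[idx]
  out
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimisation over `n_starts` random initialisations
#' (vegan's monoMDS engine); the best configuration is returned.
#'
#' @param d Distance object or symmetric matrix.
#' @param k Embedding dimension (default 2).
#' @param n_starts Random starts (default 20).
#' @param seed Integer seed for reproducibility.
#' @return An `nmds_result` list: `coordinates` tibble (`sample_id`,
#'   `NMDS1` ...), `stress`, `converged`, `n_starts`, `seed`.
#' @export
nmds <- function(d, k = 2, n_starts = 20, seed = 1) {
  dm <- stats::as.dist(d)
  if (any(!is.finite(dm))) abort("Non-finite distances in input.")
  n <- attr(dm, "Size")
  if (k < 1 || k >= n) abort("k must satisfy 1 <= k < n_samples.")
  fit <- withr::with_seed(seed,
    vegan::metaMDS(dm, k = k, trymax = n_starts, trace = 0,
                   autotransform = FALSE, wascores = FALSE))
  pts <- as_tibble(as.data.frame(fit$points), rownames = "sample_id")
  names(pts) <- c("sample_id", paste0("NMDS", seq_len(k)))
  structure(list(coordinates = pts, stress = fit$stress,
                 converged = isTRUE(fit$converged > 0) || isTRUE(fit$converged),
                 n_starts = n_starts, seed = seed, k = k),
            class = "nmds_result")
}

#' @export
print.nmds_result <- function(x, ...) {
  cat(sprintf("NMDS (k = %d): stress = %.4f over %d starts\n",
              x$k, x$stress, x$n_starts))
  invisible(x)
}

#' @rdname nmds
#' @param x An `nmds_result`.
#' @param metadata Optional metadata to colour points by `colour`.
#' @param colour Metadata column mapped to colour (default `"site"`).
#' @param ... Unused.
#' @export
autoplot.nmds_result <- function(x, metadata = NULL, colour = "site", ...) {
  pts <- x$coordinates
  if (!is.null(metadata)) {
    pts <- left_join(pts, as_tibble(metadata), by = "sample_id")
  }
  gg <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2))
  if (!is.null(metadata) && colour %in% names(pts)) {
    gg <- gg + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]))
  } else {
    gg <- gg + ggplot2::geom_point()
  }
  gg + ggplot2::labs(caption = sprintf("stress = %.3f", x$stress)) +
    ggplot2::theme_minimal()
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate analysis of variance (pseudo-F from among- and
#' within-group sums of squared distances, p by label permutation), via
#' `vegan::adonis2`.
#'
#' @param d Distance object or symmetric matrix.
#' @param groups Group label per sample (in distance-label order).
#' @param n_perm Number of permutations (default 999, minimum 99).
#' @param seed Integer seed.
#' @return A tibble: `method`, `statistic` (pseudo-F), `df`, `p_value`,
#'   `n_perm`.
#' @export
permanova <- function(d, groups, n_perm = 999, seed = 1) {
  dm <- stats::as.dist(d)
  groups <- as.factor(groups)
  if (length(groups) != attr(dm, "Size")) {
    abort("groups length must match the number of samples in d.")
  }
  tab <- table(groups)
  if (length(tab) < 2) abort("Need at least 2 groups.")
  if (any(tab < 2)) {
    abort(paste0("Group(s) of size 1: ",
                 paste(names(tab)[tab < 2], collapse = ", ")))
  }
  if (n_perm < 99) abort("n_perm must be >= 99.")
  df <- data.frame(groups = groups)
  fit <- withr::with_seed(seed,
    vegan::adonis2(dm ~ groups, data = df, permutations = n_perm))
  tibble(method = "PERMANOVA (Bray-Curtis)",
         statistic = fit$F[1], df = fit$Df[1],
         p_value = fit$`Pr(>F)`[1], n_perm = n_perm)
}

#' One-way ANOVA
#'
#' Classical F test of equal group means, applied to alpha-diversity indices
#' or single environmental variables across sites or seasons.
#'
#' @param values Numeric response vector.
#' @param groups Group label per observation.
#' @return A tibble: `method`, `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
one_way_anova <- function(values, groups) {
  groups <- as.factor(groups)
  if (length(values) != length(groups)) abort("values and groups must align.")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("Need >= 2 groups with >= 2 observations each.")
  }
  if (all(tapply(values, groups, var) == 0)) {
    abort("Zero within-group variance in every group; F undefined.")
  }
  a <- anova(lm(values ~ groups))
  tibble(method = "one-way ANOVA", statistic = a$`F value`[1],
         df1 = a$Df[1], df2 = a$Df[2], p_value = a$`Pr(>F)`[1])
}

#' ANOVA of each environmental variable across groups
#'
#' @param env Env tibble.
#' @param metadata Sample metadata.
#' @param by Grouping column (`"site"` or `"season"`).
#' @return Tibble with one row per variable: `variable`, `statistic`,
#'   `df1`, `df2`, `p_value`.
#' @export
env_anova <- function(env, metadata, by = "site") {
  metadata <- validate_metadata(metadata)
  env <- validate_env(env)
  g <- metadata[[by]][match(env$sample_id, metadata$sample_id)]
  purrr::map_dfr(env_variables(env), function(v) {
    res <- one_way_anova(env[[v]], g)
    mutate(res, variable = v, method = NULL) %>%
      select("variable", dplyr::everything())
  })
}
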