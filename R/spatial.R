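#' Great-circle distance matrix between samples
#'
#' Haversine distances (Earth radius 6371.0088 km) between sample
#' coordinates; replicates at one site are 0 km apart.
#'
#' @param metadata Sample metadata with `latitude`/`longitude`.
#' @return A [stats::dist] object in kilometres, labelled by sample id.
#' @export
haversine_matrix <- function(metadata) {
  metadata <- validate_metadata(metadata)
  bad <- metadata$sample_id[!is.finite(metadata$latitude) |
                              !is.finite(metadata$longitude)]
  if (length(bad) > 0) {
    abort(paste0("Missing coordinates for sample(s): ",
                 paste(bad, collapse = ", ")))
  }
  xy <- as.matrix(metadata[, c("longitude", "latitude")])
  m <- geosphere::distm(xy, fun = function(a, b) {
    geosphere::distHaversine(a, b, r = 6371.0088)
  })
  rownames(m) <- colnames(m) <- metadata$sample_id
  stats::as.dist(m)
}

#' Environmental (Euclidean) distance matrix
#'
#' Euclidean distance over z-scored environmental variables, so each
#' variable contributes on a comparable scale regardless of its units.
#'
#' @param env Env tibble.
#' @param variables Variables to use (default: all numeric columns).
#' @param standardize Z-score each variable first (default `TRUE`).
#' @return A [stats::dist] object labelled by sample id.
#' @export
env_distance <- function(env, variables = NULL, standardize = TRUE) {
  env <- validate_env(env)
  if (is.null(variables)) variables <- env_variables(env)
  missing_v <- setdiff(variables, names(env))
  if (length(missing_v) > 0) {
    abort(paste0("Variable(s) absent from env table: ",
                 paste(missing_v, collapse = ", ")))
  }
  m <- as.matrix(env[, variables, drop = FALSE])
  if (any(!is.finite(m))) abort("Non-finite environmental values.")
  if (standardize) {
    sds <- apply(m, 2, sd)
    if (any(sds == 0)) {
      abort(paste0("Zero-variance variable(s): ",
                   paste(variables[sds == 0], collapse = ", ")))
    }
    m <- scale(m)
  }
  rownames(m) <- env$sample_id
  dist(m)
}

# correlation between upper triangles with simultaneous row/col permutation
# of the second matrix; returns observed r and the permutation distribution
mantel_perm <- function(m1, m2, method, n_perm, seed) {
  ut <- upper.tri(m1)
  v1 <- m1[ut]
  r_obs <- cor(v1, m2[ut], method = method)
  n <- nrow(m1)
  r_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n)
      cor(v1, m2[idx, idx][ut], method = method)
    }, numeric(1))
  })
  list(r_obs = r_obs, r_perm = r_perm)
}

#' Mantel test between two distance matrices
#'
#' Correlation between the vectorised upper triangles, with significance by
#' simultaneous row/column permutation of one matrix. Two-sided by default
#' (`p = (1 + #\{|r*| >= |r|\}) / (1 + n_perm)`); `alternative = "greater"`
#' gives the classical one-sided test.
#'
#' @param d1,d2 Distance objects or symmetric matrices over the same samples.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param n_perm Permutations (default 999, minimum 99).
#' @param seed Integer seed.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @return A tibble: `r`, `p_value`, `method`, `alternative`, `n_perm`,
#'   `seed`.
#' @export
mantel_test <- function(d1, d2, method = c("pearson", "spearman"),
                        n_perm = 999, seed = 1,
                        alternative = c("two.sided", "greater")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  if (n_perm < 99) abort("n_perm must be >= 99.")
  m1 <- as.matrix(d1)
  m2 <- as.matrix(d2)
  if (!all(dim(m1) == dim(m2))) abort("Distance matrices differ in size.")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2))) {
    if (!identical(rownames(m1), rownames(m2))) {
      if (!setequal(rownames(m1), rownames(m2))) {
        abort("Distance matrices have different sample labels.")
      }
      m2 <- m2[rownames(m1), rownames(m1)]
    }
  }
  if (sd(m1[upper.tri(m1)]) == 0 || sd(m2[upper.tri(m2)]) == 0) {
    abort("Constant distance matrix; Mantel r undefined.")
  }
  mp <- mantel_perm(m1, m2, method, n_perm, seed)
  p <- if (alternative == "two.sided") {
    (1 + sum(abs(mp$r_perm) >= abs(mp$r_obs))) / (1 + n_perm)
  } else {
    (1 + sum(mp$r_perm >= mp$r_obs)) / (1 + n_perm)
  }
  tibble(r = mp$r_obs, p_value = p, method = method,
         alternative = alternative, n_perm = n_perm, seed = seed)
}

#' Mantel tests of community vs each environmental variable, by group
#'
#' Runs one Mantel test per environmental variable (distance on that single
#' z-scored variable) against the community dissimilarity, optionally within
#' sample subsets defined by a metadata column — the per-site / per-season
#' panel layout of reservoir surveys.
#'
#' @param otu Wide OTU tibble.
#' @param env Env tibble.
#' @param metadata Sample metadata.
#' @param by Optional grouping column (`"site"` or `"season"`); `NULL` tests
#'   all samples together.
#' @param method,n_perm,seed Passed to [mantel_test()].
#' @return Tibble with `group`, `variable`, `r`, `p_value`, ...
#' @export
mantel_env_panel <- function(otu, env, metadata, by = NULL,
                             method = "spearman", n_perm = 999, seed = 1) {
  metadata <- validate_metadata(metadata, otu)
  env <- validate_env(env, otu)
  samples <- otu_samples(otu)
  groups <- if (is.null(by)) {
    list(all = samples)
  } else {
    split(metadata$sample_id, metadata[[by]])
  }
  purrr::imap_dfr(groups, function(ids, gname) {
    ids <- intersect(samples, ids)
    sub_otu <- otu[, c("otu_id", ids)]
    sub_otu <- sub_otu[rowSums(otu_counts(sub_otu)) > 0, ]
    dcomm <- bray_curtis(sub_otu)
    sub_env <- env[match(ids, env$sample_id), ]
    purrr::map_dfr(env_variables(sub_env), function(v) {
      if (sd(sub_env[[v]]) == 0) return(NULL)
      denv <- env_distance(sub_env, v)
      res <- mantel_test(dcomm, denv, method = method, n_perm = n_perm,
                         seed = seed)
      mutate(res, group = gname, variable = v) %>%
        select("group", "variable", dplyr::everything())
    })
  })
}

#' Distance-decay regression
#'
#' OLS of community dissimilarity on a predictor distance (geographic km or
#' environmental Euclidean) over the unique sample pairs, with a
#' Mantel-style permutation p-value since pairs are not independent. The
#' similarity-decay slope is the negation of the dissimilarity slope and is
#' reported alongside.
#'
#' @param comm Community distance (e.g. [bray_curtis()]).
#' @param pred Predictor distance (e.g. [haversine_matrix()],
#'   [env_distance()]).
#' @param n_perm Permutations for the p-value (default 999).
#' @param seed Integer seed.
#' @return A `decay_fit` list with `slope`, `intercept`, `r_squared`,
#'   `p_value`, `similarity_slope`, `n_pairs`, and the pair table.
#' @export
distance_decay <- function(comm, pred, n_perm = 999, seed = 1) {
  m1 <- as.matrix(comm)
  m2 <- as.matrix(pred)
  if (!all(dim(m1) == dim(m2))) abort("Distance matrices differ in size.")
  if (!is.null(rownames(m1)) && !is.null(rownames(m2)) &&
      !identical(rownames(m1), rownames(m2))) {
    if (!setequal(rownames(m1), rownames(m2))) {
      abort("Distance matrices have different sample labels.")
    }
    m2 <- m2[rownames(m1), rownames(m1)]
  }
  ut <- upper.tri(m1)
  y <- m1[ut]
  x <- m2[ut]
  if (sd(x) == 0) abort("Predictor distances are all equal; fit undefined.")
  fit <- lm(y ~ x)
  mp <- mantel_perm(m1, m2, "pearson", n_perm, seed)
  p <- (1 + sum(abs(mp$r_perm) >= abs(mp$r_obs))) / (1 + n_perm)
  pairs <- dist_pairs(comm, "dissimilarity")
  pairs$predictor <- x
  structure(list(slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 p_value = p,
                 similarity_slope = -unname(coef(fit)[2]),
                 n_pairs = length(y), n_perm = n_perm, seed = seed,
                 pairs = pairs),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat(sprintf(
    "Distance decay: slope = %.4g, r^2 = %.3f, p = %.4g (%d pairs)\n",
    x$slope, x$r_squared, x$p_value, x$n_pairs))
  invisible(x)
}

#' @rdname distance_decay
#' @param x A `decay_fit`.
#' @param ... Unused.
#' @export
autoplot.decay_fit <- function(x, ...) {
  ggplot2::ggplot(x$pairs, ggplot2::aes(x = .data$predictor,
                                        y = .data$dissimilarity)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = x$slope, intercept = x$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "Predictor distance", y = "Community dissimilarity",
                  caption = sprintf("slope = %.3g, p = %.3g", x$slope,
                                    x$p_value)) +
    ggplot2::theme_minimal()
}

#' @export
tidy.decay_fit <- function(x, ...) {
  tibble(term = c("intercept", "slope"),
         estimate = c(x$intercept, x$slope))
}

#' @export
glance.decay_fit <- function(x, ...) {
  tibble(slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, p_value = x$p_value,
         similarity_slope = x$similarity_slope, n_pairs = x$n_pairs)
}
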