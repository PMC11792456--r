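#' Per-OTU occurrence statistics for the neutral model
#'
#' @param otu Wide OTU tibble.
#' @return A tibble with `otu_id`, `p` (mean relative abundance across
#'   samples), `f` (fraction of samples where detected); the mean library
#'   size `N_T` and sample count are attached as attributes `N_T` and
#'   `n_samples`. OTUs absent everywhere are dropped with a warning.
#' @export
occurrence_stats <- function(otu) {
  m <- otu_counts(otu)
  if (ncol(m) < 5) warn("Fewer than 5 samples; occurrence frequencies are coarse.")
  rel <- sweep(m, 2, colSums(m), "/")
  p <- rowMeans(rel)
  f <- rowMeans(m > 0)
  absent <- p == 0
  if (any(absent)) {
    warn(paste0(sum(absent), " OTU(s) absent from every sample were dropped."))
  }
  out <- tibble(otu_id = rownames(m)[!absent], p = unname(p[!absent]),
                f = unname(f[!absent]))
  attr(out, "N_T") <- mean(colSums(m))
  attr(out, "n_samples") <- ncol(m)
  out
}

#' Fit the Sloan neutral community model
#'
#' Predicts each OTU's occurrence frequency from its regional mean relative
#' abundance, `f_hat_i = 1 - pbeta(d; N_T * m * p_i, N_T * m * (1 - p_i))`,
#' and estimates the migration rate `m` by least squares of observed against
#' predicted frequencies. A 95% binomial envelope (Wilson interval at
#' `n = n_samples`) around the prediction partitions OTUs into above /
#' within / below classes.
#'
#' @param x An OTU tibble or the output of [occurrence_stats()].
#' @param d Detection limit as a relative abundance (default one read,
#'   `1 / N_T`).
#' @return An `ncm_fit` list: `m`, `r_squared`, `N_T`, `d`, `n_samples`,
#'   and a per-OTU tibble `otus` with predicted frequency, Wilson bounds
#'   and partition.
#' @export
fit_ncm <- function(x, d = NULL) {
  stats_tbl <- if (is_tibble(x) && all(c("p", "f") %in% names(x)) &&
                   !is.null(attr(x, "N_T"))) x else occurrence_stats(x)
  nt <- attr(stats_tbl, "N_T")
  n_samples <- attr(stats_tbl, "n_samples")
  if (is.null(d)) d <- 1 / nt
  p <- stats_tbl$p
  f <- stats_tbl$f
  informative <- sum(f > 0 & f < 1)
  if (informative < 10) {
    warn("Fewer than 10 OTUs with intermediate occurrence; m is weakly identified.")
  }
  pred_f <- function(m) 1 - pbeta(d, nt * m * p, nt * m * (1 - p))
  sse <- function(m) sum((f - pred_f(m))^2)
  opt <- optimize(sse, interval = c(1e-8, 1))
  m_hat <- opt$minimum
  sst <- sum((f - mean(f))^2)
  if (sst == 0) abort("Occurrence frequencies are constant; NCM fit undefined.")
  r2 <- 1 - opt$objective / sst
  fh <- pred_f(m_hat)
  wil <- wilson_interval(fh, n_samples)
  partition <- dplyr::case_when(
    f > wil$upper ~ "above",
    f < wil$lower ~ "below",
    TRUE ~ "within"
  )
  otus <- stats_tbl %>%
    mutate(predicted = fh, ci_lower = wil$lower, ci_upper = wil$upper,
           partition = partition)
  structure(list(m = m_hat, r_squared = r2, N_T = nt, d = d,
                 n_samples = n_samples, otus = otus),
            class = "ncm_fit")
}

# Wilson score interval for a proportion fh at sample size n
wilson_interval <- function(fh, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  centre <- (fh + z^2 / (2 * n)) / denom
  half <- z * sqrt(fh * (1 - fh) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf("Sloan NCM: m = %.4g, R^2 = %.3f (N_T = %.0f, %d samples)\n",
              x$m, x$r_squared, x$N_T, x$n_samples))
  tab <- table(x$otus$partition)
  cat("Partition:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.ncm_fit <- function(x, ...) x$otus

#' @export
glance.ncm_fit <- function(x, ...) {
  tab <- table(factor(x$otus$partition, c("above", "within", "below")))
  tibble(m = x$m, r_squared = x$r_squared, N_T = x$N_T,
         n_samples = x$n_samples, d = x$d,
         frac_above = as.numeric(tab["above"]) / nrow(x$otus),
         frac_within = as.numeric(tab["within"]) / nrow(x$otus),
         frac_below = as.numeric(tab["below"]) / nrow(x$otus))
}

#' @rdname fit_ncm
#' @param ... Unused.
#' @export
autoplot.ncm_fit <- function(x, ...) {
  df <- x$otus %>% arrange(.data$p)
  ggplot2::ggplot(df, ggplot2::aes(x = log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(y = .data$f, colour = .data$partition),
                        alpha = 0.5, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_lower), linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_upper), linetype = "dashed") +
    ggplot2::labs(x = "log10 mean relative abundance",
                  y = "Occurrence frequency",
                  caption = sprintf("m = %.3g, R^2 = %.2f", x$m, x$r_squared)) +
    ggplot2::theme_minimal()
}

#' Null community ensemble
#'
#' Default algorithm (`"abundance"`): each null sample redraws its observed
#' library size multinomially from the pooled regional relative abundances,
#' preserving per-sample totals and the regional abundance distribution.
#' `"shuffle"` instead permutes each sample's counts over OTUs, preserving
#' per-sample richness and the count multiset.
#'
#' @param otu Wide OTU tibble.
#' @param algorithm `"abundance"` (default) or `"shuffle"`.
#' @param n_iter Number of null tables (>= 100 recommended for inference).
#' @param seed Integer seed.
#' @return List of `n_iter` count matrices (OTU x sample).
#' @export
null_communities <- function(otu, algorithm = c("abundance", "shuffle"),
                             n_iter = 100, seed = 1) {
  algorithm <- match.arg(algorithm)
  m <- otu_counts(otu)
  totals <- colSums(m)
  pool <- rowSums(m) / sum(m)
  withr::with_seed(seed, {
    lapply(seq_len(n_iter), function(i) {
      if (algorithm == "abundance") {
        null <- vapply(totals, function(n) rmultinom(1, n, pool)[, 1],
                       numeric(nrow(m)))
      } else {
        null <- apply(m, 2, function(x) x[sample.int(length(x))])
      }
      dimnames(null) <- dimnames(m)
      null
    })
  })
}

#' Modified stochasticity ratio (MST)
#'
#' For each sample pair, compares observed Bray-Curtis dissimilarity `D_ij`
#' with the mean null expectation `E_ij` over a null ensemble:
#' `MST_ij = D_ij / E_ij` when `D_ij <= E_ij`, else
#' `(1 - D_ij) / (1 - E_ij)`. Values near 1 indicate assembly
#' indistinguishable from the null (stochastic); the group mean is
#' classified against 0.5.
#'
#' @param otu Wide OTU tibble.
#' @param nulls Optional ensemble from [null_communities()]; generated with
#'   `n_iter` and `seed` when `NULL`.
#' @param n_iter,seed,algorithm Null-model settings used when `nulls` is
#'   `NULL`.
#' @return An `mst_result` list: `pairs` tibble (per-pair `observed`,
#'   `expected`, `mst`), `mean_mst`, `classification`
#'   (`"stochastic"`/`"deterministic"`), and the null-model settings.
#' @export
mst <- function(otu, nulls = NULL, n_iter = 100, seed = 1,
                algorithm = "abundance") {
  m <- otu_counts(otu)
  if (is.null(nulls)) {
    nulls <- null_communities(otu, algorithm = algorithm,
                              n_iter = n_iter, seed = seed)
  }
  d_obs <- as.matrix(vegan::vegdist(t(sweep(m, 2, colSums(m), "/")),
                                    method = "bray"))
  e_sum <- matrix(0, ncol(m), ncol(m))
  for (null in nulls) {
    rel <- sweep(null, 2, colSums(null), "/")
    e_sum <- e_sum + as.matrix(vegan::vegdist(t(rel), method = "bray"))
  }
  e_mean <- e_sum / length(nulls)
  ut <- upper.tri(d_obs)
  idx <- which(ut, arr.ind = TRUE)
  d <- d_obs[ut]
  e <- e_mean[ut]
  ok <- e > 0 & e < 1
  if (any(!ok)) {
    warn(paste0(sum(!ok), " pair(s) with degenerate null expectation excluded."))
  }
  mst_v <- ifelse(d <= e, d / pmax(e, .Machine$double.eps),
                  (1 - d) / (1 - e))
  pairs <- tibble(sample_1 = colnames(m)[idx[, 1]],
                  sample_2 = colnames(m)[idx[, 2]],
                  observed = d, expected = e, mst = mst_v)[ok, ]
  mean_mst <- mean(pairs$mst)
  structure(list(pairs = pairs, mean_mst = mean_mst,
                 classification = ifelse(mean_mst > 0.5, "stochastic",
                                         "deterministic"),
                 null = list(algorithm = algorithm, n_iter = length(nulls),
                             seed = seed,
                             formula = "MST = D/E if D <= E else (1-D)/(1-E)")),
            class = "mst_result")
}

#' @export
print.mst_result <- function(x, ...) {
  cat(sprintf("MST: mean = %.3f over %d pairs -> %s assembly\n",
              x$mean_mst, nrow(x$pairs), x$classification))
  invisible(x)
}

#' @export
glance.mst_result <- function(x, ...) {
  tibble(mean_mst = x$mean_mst, n_pairs = nrow(x$pairs),
         classification = x$classification,
         null_algorithm = x$null$algorithm, n_iter = x$null$n_iter)
}

#' Per-group assembly analysis
#'
#' Fits the neutral model and computes the MST within each level of a
#' metadata column (one panel per site), plus a pooled fit over all
#' samples.
#'
#' @param otu Wide OTU tibble.
#' @param metadata Sample metadata.
#' @param by Grouping column (default `"site"`).
#' @param n_iter,seed Null-model settings for [mst()].
#' @return A tibble with one row per group (plus `"pooled"`): `group`,
#'   `m`, `r_squared`, `mean_mst`, `classification`.
#' @export
assembly_by_group <- function(otu, metadata, by = "site", n_iter = 100,
                              seed = 1) {
  metadata <- validate_metadata(metadata, otu)
  groups <- split(metadata$sample_id, metadata[[by]])
  groups$pooled <- otu_samples(otu)
  purrr::imap_dfr(groups, function(ids, gname) {
    sub <- otu[, c("otu_id", intersect(otu_samples(otu), ids))]
    sub <- sub[rowSums(otu_counts(sub)) > 0, ]
    fit <- suppressWarnings(fit_ncm(sub))
    ms <- suppressWarnings(mst(sub, n_iter = n_iter, seed = seed))
    tibble(group = gname, m = fit$m, r_squared = fit$r_squared,
           mean_mst = ms$mean_mst, classification = ms$classification)
  })
}
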