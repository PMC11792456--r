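#' DCA gradient-length check
#'
#' Detrended correspondence analysis of the community matrix; the length of
#' the first axis in species-turnover (SD) units decides between a linear
#' (RDA) and unimodal (CCA) constrained-ordination model. Lengths below the
#' threshold (default 3) favour the linear model.
#'
#' @param otu Wide OTU tibble.
#' @param threshold Gradient-length threshold in SD units (default 3).
#' @return A tibble: `axis1_length`, `model_choice`
#'   (`"linear"`/`"unimodal"`), `threshold`.
#' @export
dca_gradient_length <- function(otu, threshold = 3) {
  m <- otu_counts(otu)
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 3) abort("Need >= 2 OTUs and >= 3 samples for DCA.")
  dec <- vegan::decorana(t(m))
  sc <- vegan::scores(dec, display = "sites")
  len <- diff(range(sc[, 1]))
  tibble(axis1_length = len,
         model_choice = ifelse(len < threshold, "linear", "unimodal"),
         threshold = threshold)
}

#' Redundancy analysis of community composition on environmental predictors
#'
#' Hellinger-transforms the community matrix (configurable), z-scores the
#' predictors, and fits RDA. Axis shares are reported as percentages of the
#' constrained variance.
#'
#' @param otu Wide OTU tibble.
#' @param env Env tibble.
#' @param variables Predictor columns (default: all env variables).
#' @param transform `"hellinger"` (default), `"chord"`, or `"none"`.
#' @param standardize_x Z-score predictors (default `TRUE`).
#' @return An `rda_fit` list wrapping the vegan model plus tidied pieces:
#'   `eigenvalues`, `axis_percent` (of constrained variance),
#'   `constrained_proportion` (of total variance), `site_scores`,
#'   `species_scores`, `biplot`.
#' @export
rda_fit <- function(otu, env, variables = NULL,
                    transform = c("hellinger", "chord", "none"),
                    standardize_x = TRUE) {
  transform <- match.arg(transform)
  env <- validate_env(env, otu)
  if (is.null(variables)) variables <- env_variables(env)
  m <- t(otu_counts(otu))   # samples x OTUs
  env <- env[match(rownames(m), env$sample_id), ]
  x <- as.matrix(env[, variables, drop = FALSE])
  if (nrow(m) <= ncol(x) + 1) {
    abort("Need n_samples > n_predictors + 1 for RDA.")
  }
  qrx <- qr(scale(x, scale = FALSE))
  if (qrx$rank < ncol(x)) {
    drop_cols <- variables[-seq_len(qrx$rank)]
    abort(paste0("Predictors are rank deficient; collinear column(s) near: ",
                 paste(drop_cols, collapse = ", ")))
  }
  y <- switch(transform,
              hellinger = vegan::decostand(m, "hellinger"),
              chord = vegan::decostand(m, "normalize"),
              none = m)
  if (standardize_x) x <- scale(x)
  xdf <- as.data.frame(x)
  fit <- vegan::rda(y ~ ., data = xdf)
  eig <- fit$CCA$eig
  sc <- vegan::scores(fit, display = c("sites", "species", "bp"),
                      choices = seq_len(min(2, length(eig))), scaling = 2)
  structure(list(
    model = fit,
    transform = transform,
    variables = variables,
    eigenvalues = as.numeric(eig),
    axis_percent = as.numeric(100 * eig / sum(eig)),
    constrained_proportion = fit$CCA$tot.chi / fit$tot.chi,
    site_scores = as_tibble(as.data.frame(sc$sites), rownames = "sample_id"),
    species_scores = as_tibble(as.data.frame(sc$species), rownames = "otu_id"),
    biplot = as_tibble(as.data.frame(sc$biplot), rownames = "variable")
  ), class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf(
    "RDA (%s-transformed): constrained axes explain %.1f%% of total variance\n",
    x$transform, 100 * x$constrained_proportion))
  cat("Axis shares of constrained variance (%):",
      paste(sprintf("%.2f", head(x$axis_percent, 4)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.rda_fit <- function(x, ...) {
  tibble(axis = paste0("RDA", seq_along(x$eigenvalues)),
         eigenvalue = x$eigenvalues,
         percent_constrained = x$axis_percent)
}

#' @export
glance.rda_fit <- function(x, ...) {
  tibble(constrained_proportion = x$constrained_proportion,
         n_axes = length(x$eigenvalues),
         axis1_percent = x$axis_percent[1],
         axis2_percent = ifelse(length(x$axis_percent) > 1,
                                x$axis_percent[2], NA_real_))
}

#' @rdname rda_fit
#' @param x An `rda_fit`.
#' @param ... Unused.
#' @export
autoplot.rda_fit <- function(x, ...) {
  arrow_scale <- max(abs(as.matrix(x$site_scores[, -1]))) /
    max(abs(as.matrix(x$biplot[, -1])))
  bp <- x$biplot
  bp[, -1] <- bp[, -1] * arrow_scale
  ax <- names(x$site_scores)[2:3]
  ggplot2::ggplot(x$site_scores,
                  ggplot2::aes(x = .data[[ax[1]]], y = .data[[ax[2]]])) +
    ggplot2::geom_point() +
    ggplot2::geom_segment(data = bp,
                          ggplot2::aes(x = 0, y = 0, xend = .data[[ax[1]]],
                                       yend = .data[[ax[2]]]),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          colour = "firebrick") +
    ggplot2::geom_text(data = bp,
                       ggplot2::aes(label = .data$variable),
                       colour = "firebrick", vjust = -0.5, size = 3) +
    ggplot2::labs(x = sprintf("RDA1 (%.1f%%)", x$axis_percent[1]),
                  y = sprintf("RDA2 (%.1f%%)",
                              ifelse(length(x$axis_percent) > 1,
                                     x$axis_percent[2], 0))) +
    ggplot2::theme_minimal()
}

#' Permutation significance of an RDA model
#'
#' Monte-Carlo test of the constrained ordination: overall pseudo-F, or
#' marginal tests per predictor (reduced-model residual permutation).
#'
#' @param fit An [rda_fit()] object.
#' @param scope `"overall"` (default) or `"margin"`.
#' @param n_perm Permutations (default 999, minimum 99).
#' @param seed Integer seed.
#' @return A tibble with `term`, `statistic` (F), `p_value`, `n_perm`.
#' @export
rda_significance <- function(fit, scope = c("overall", "margin"),
                             n_perm = 999, seed = 1) {
  scope <- match.arg(scope)
  if (n_perm < 99) abort("n_perm must be >= 99.")
  an <- withr::with_seed(seed, {
    if (scope == "overall") {
      anova(fit$model, permutations = n_perm)
    } else {
      anova(fit$model, by = "margin", permutations = n_perm)
    }
  })
  terms <- rownames(an)
  keep <- terms != "Residual"
  tibble(term = if (scope == "overall") "overall" else terms[keep],
         statistic = an$F[keep], p_value = an$`Pr(>F)`[keep],
         n_perm = n_perm)
}
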