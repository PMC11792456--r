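#' Default correlations with chlorophyll a for Chinese lakes and reservoirs
#'
#' Correlation coefficients `r` between each TLI evaluation parameter and the
#' reference parameter chlorophyll a, as standardised for Chinese lakes and
#' reservoirs: Chl a 1, TP 0.84, TN 0.82, SD -0.83, COD_Mn 0.83.
#'
#' @return Named numeric vector in parameter order
#'   (`Chl_a`, `TP`, `TN`, `SD`, `COD_Mn`).
#' @export
tli_reference_r <- function() {
  c(Chl_a = 1, TP = 0.84, TN = 0.82, SD = -0.83, COD_Mn = 0.83)
}

#' Normalised TLI parameter weights
#'
#' `W_j = r_j^2 / sum(r^2)`, with chlorophyll a as the reference parameter
#' (r = 1). The sign of r is irrelevant to the weight.
#'
#' @param r Named vector of correlations with Chl a
#'   (default [tli_reference_r()]).
#' @return A tibble with `parameter`, `r`, `r2`, `weight`
#'   (`sum(weight) == 1`).
#' @export
tli_weights <- function(r = tli_reference_r()) {
  if (length(r) < 2) abort("Need at least 2 evaluation parameters.")
  if (all(r == 0)) abort("All correlations are zero; weights undefined.")
  if (is.null(names(r))) names(r) <- paste0("param_", seq_along(r))
  tibble(parameter = names(r), r = as.numeric(r), r2 = as.numeric(r)^2,
         weight = as.numeric(r)^2 / sum(r^2))
}

# sub-index coefficients: TLI(x) = 10 * (a + b * ln x)
tli_coefficients <- function() {
  tibble(parameter = c("Chl_a", "TP", "TN", "SD", "COD_Mn"),
         a = c(2.5, 9.436, 5.453, 5.118, 0.109),
         b = c(1.086, 1.624, 1.694, -1.94, 2.661))
}

#' TLI sub-index for one parameter
#'
#' `TLI(j) = 10 * (a_j + b_j * ln(x))` with the standard coefficients for
#' Chl a (mg/m3), TP, TN, COD_Mn (mg/L) and Secchi transparency SD (m; the
#' only decreasing sub-index).
#'
#' @param parameter One of `"Chl_a"`, `"TP"`, `"TN"`, `"SD"`, `"COD_Mn"`.
#' @param value Measured value, strictly positive (log domain).
#' @return The sub-index score (vectorised over `value`).
#' @export
tli_subindex <- function(parameter, value) {
  cf <- tli_coefficients()
  if (!parameter %in% cf$parameter) {
    abort(paste0("Unknown TLI parameter: ", parameter))
  }
  if (any(!is.finite(value)) || any(value <= 0)) {
    abort(paste0("TLI(", parameter, ") requires strictly positive values (ln domain)."))
  }
  row <- cf[cf$parameter == parameter, ]
  10 * (row$a + row$b * log(value))
}

#' Composite trophic level index
#'
#' `TLI = sum_j W_j * TLI(j)`. All five standard sub-indices are expected;
#' with `renormalize = TRUE` a subset is accepted and the corresponding
#' weights are rescaled to sum 1.
#'
#' @param subindices Named numeric vector of sub-index scores.
#' @param weights Weight table from [tli_weights()].
#' @param renormalize Allow a parameter subset (default `FALSE`).
#' @return The composite TLI.
#' @export
composite_tli <- function(subindices, weights = tli_weights(),
                          renormalize = FALSE) {
  w <- setNames(weights$weight, weights$parameter)
  missing_p <- setdiff(names(w), names(subindices))
  if (length(missing_p) > 0) {
    if (!renormalize) {
      abort(paste0("Missing sub-index value(s): ",
                   paste(missing_p, collapse = ", "),
                   " (set renormalize = TRUE to use a subset)."))
    }
    w <- w[intersect(names(w), names(subindices))]
    w <- w / sum(w)
  }
  sum(w * subindices[names(w)])
}

#' Grade trophic status from a TLI value
#'
#' Chinese lake/reservoir grading: TLI < 30 oligotrophic; 30 <= TLI < 50
#' mesotrophic; TLI > 50 eutrophic, subdivided into light (50-60], middle
#' (60-70] and hyper (> 70). TLI exactly 50 sits between the printed bands
#' and is graded as mesotrophic-boundary with a flag.
#'
#' @param tli Numeric vector of composite TLI values.
#' @return A tibble with `tli`, `status` (main class), `subclass`
#'   (eutrophic band or `NA`), `boundary` (logical flag for TLI == 50).
#' @export
classify_trophic_status <- function(tli) {
  if (any(!is.finite(tli))) abort("TLI must be finite.")
  status <- dplyr::case_when(
    tli < 30 ~ "Oligotrophic",
    tli < 50 ~ "Mesotrophic",
    tli == 50 ~ "Mesotrophic",
    TRUE ~ "Eutrophic"
  )
  subclass <- dplyr::case_when(
    tli > 70 ~ "Hyper eutrophic",
    tli > 60 ~ "Middle eutrophic",
    tli > 50 ~ "Light eutrophic",
    TRUE ~ NA_character_
  )
  tibble(tli = tli, status = status, subclass = subclass,
         boundary = tli == 50)
}

#' Trophic level index per sample or per site
#'
#' Computes the five sub-indices and the weighted composite for each sample,
#' then (optionally) averages per site. With `aggregate = "mean_concentration"`
#' the per-site mean concentrations are scored instead (aggregation before
#' the log transform).
#'
#' @param env Env tibble with `Chl_a`, `TP`, `TN`, `SD`, `COD_Mn`.
#' @param metadata Optional metadata; required for `by = "site"`.
#' @param weights Weight table from [tli_weights()].
#' @param by `"site"` (default) or `"sample"`.
#' @param aggregate `"sample_then_mean"` (score each sample, then average;
#'   default) or `"mean_concentration"`.
#' @return A tibble with one row per unit: sub-index columns
#'   (`tli_Chl_a` ...), `tli`, `status`, `subclass`, `boundary`.
#' @export
tli_score <- function(env, metadata = NULL, weights = tli_weights(),
                      by = c("site", "sample"),
                      aggregate = c("sample_then_mean", "mean_concentration")) {
  by <- match.arg(by)
  aggregate <- match.arg(aggregate)
  env <- validate_env(env)
  need <- c("Chl_a", "TP", "TN", "SD", "COD_Mn")
  missing_v <- setdiff(need, names(env))
  if (length(missing_v) > 0) {
    abort(paste0("Env table missing TLI parameter(s): ",
                 paste(missing_v, collapse = ", ")))
  }

  score_rows <- function(df, unit_ids, unit_name) {
    sub <- purrr::map_dfc(need, function(p) {
      out <- tibble(tli_subindex(p, df[[p]]))
      names(out) <- paste0("tli_", p)
      out
    })
    comp <- vapply(seq_len(nrow(sub)), function(i) {
      composite_tli(setNames(as.numeric(sub[i, ]), need), weights)
    }, numeric(1))
    out <- tibble(!!unit_name := unit_ids) %>% dplyr::bind_cols(sub)
    out$tli <- comp
    out
  }

  if (by == "sample") {
    res <- score_rows(env, env$sample_id, "sample_id")
  } else {
    if (is.null(metadata)) abort("metadata is required for by = 'site'.")
    metadata <- validate_metadata(metadata)
    site <- metadata$site[match(env$sample_id, metadata$sample_id)]
    if (any(is.na(site))) abort("Env sample_id(s) missing from metadata.")
    if (aggregate == "mean_concentration") {
      mdf <- env %>% mutate(site = site) %>% group_by(.data$site) %>%
        summarise(across(all_of(need), mean), .groups = "drop")
      res <- score_rows(mdf, mdf$site, "site")
    } else {
      per_sample <- score_rows(env, env$sample_id, "sample_id") %>%
        mutate(site = site)
      res <- per_sample %>% group_by(.data$site) %>%
        summarise(across(dplyr::starts_with("tli"), mean), .groups = "drop")
    }
  }
  grading <- classify_trophic_status(res$tli)
  res %>% mutate(status = grading$status, subclass = grading$subclass,
                 boundary = grading$boundary)
}

#' Linear regressions of TLI on predictors
#'
#' One ordinary-least-squares fit per predictor column, used both for TLI
#' versus environmental factors and TLI versus diversity indices.
#'
#' @param tli Numeric response vector (composite TLI per unit).
#' @param predictors Data frame of numeric predictor columns, rows aligned
#'   with `tli`.
#' @return A tibble with one row per predictor: `predictor`, `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`.
#' @export
tli_regressions <- function(tli, predictors) {
  predictors <- as_tibble(predictors)
  if (nrow(predictors) != length(tli)) abort("predictors rows must match tli length.")
  if (length(tli) < 3) abort("Need at least 3 paired observations.")
  purrr::map_dfr(names(predictors), function(v) {
    x <- predictors[[v]]
    ok <- is.finite(x) & is.finite(tli)
    if (var(x[ok]) == 0) {
      abort(paste0("Predictor '", v, "' is constant; regression undefined."))
    }
    fit <- lm(tli[ok] ~ x[ok])
    sm <- summary(fit)
    tibble(predictor = v, slope = unname(coef(fit)[2]),
           intercept = unname(coef(fit)[1]),
           r_squared = sm$r.squared,
           p_value = sm$coefficients[2, 4], n = sum(ok))
  })
}
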