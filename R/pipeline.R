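#' Read a pipeline configuration
#'
#' A configuration is a plain list (or YAML file) with an `inputs` block
#' (`otu`, `metadata`, `env`, optional `taxonomy` paths) *or* a `simulate`
#' block of [sim_params()] arguments, an optional `stages` character vector
#' selecting stages, and optional per-stage parameter blocks
#' (`permutations`, `seed`, network thresholds, ...).
#'
#' @param x A list or path to a YAML file.
#' @return The validated config list.
#' @export
read_pipeline_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (!is.list(cfg)) abort("Config must be a list or a YAML file path.")
  if (is.null(cfg$inputs) && is.null(cfg$simulate)) {
    abort("Config needs an 'inputs' block or a 'simulate' block.")
  }
  cfg$stages <- cfg$stages %||% pipeline_stages()
  unknown <- setdiff(cfg$stages, pipeline_stages())
  if (length(unknown) > 0) {
    abort(paste0("Unknown stage(s): ", paste(unknown, collapse = ", ")))
  }
  cfg$seed <- cfg$seed %||% 1L
  cfg$permutations <- cfg$permutations %||% 999L
  cfg$null_iters <- cfg$null_iters %||% 100L
  cfg
}

#' Stage names of the analysis pipeline, in execution order
#' @return Character vector of stage ids.
#' @export
pipeline_stages <- function() {
  c("composition", "diversity", "env_anova", "decay", "mantel",
    "ordination", "network", "tli", "assembly")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in the order composition, diversity,
#' environmental ANOVA, distance decay, Mantel, DCA/RDA, networks, TLI,
#' assembly. A failing stage is recorded in the report and later
#' independent stages still run.
#'
#' @param config A config list or YAML path (see [read_pipeline_config()]).
#' @return A `pipeline_report` list: `results` (one bundle per executed
#'   stage), `errors`, `config`, `stages_run`.
#' @export
run_pipeline <- function(config) {
  cfg <- read_pipeline_config(config)
  if (!is.null(cfg$simulate)) {
    params <- do.call(sim_params, cfg$simulate)
    ds <- simulate_dataset(params)
    otu <- ds$otu; metadata <- ds$metadata; env <- ds$env
    taxonomy <- NULL
  } else {
    otu <- read_otu_table(cfg$inputs$otu)
    metadata <- read_metadata(cfg$inputs$metadata)
    env <- read_env(cfg$inputs$env)
    taxonomy <- if (!is.null(cfg$inputs$taxonomy)) {
      as_tibble(read_delim_sniff(cfg$inputs$taxonomy))
    }
  }
  metadata <- validate_metadata(metadata, otu)
  env <- validate_env(env, otu)

  results <- list()
  errors <- list()
  run_stage <- function(name, expr) {
    if (!name %in% cfg$stages) return(invisible(NULL))
    res <- tryCatch(expr, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[name]] <<- conditionMessage(res)
    } else {
      results[[name]] <<- res
    }
    invisible(NULL)
  }
  np <- cfg$permutations
  seed <- cfg$seed

  run_stage("composition", {
    if (is.null(taxonomy)) {
      list(note = "no taxonomy supplied; composition skipped")
    } else {
      list(by_site = aggregate_composition(otu, taxonomy, metadata, by = "site"),
           by_season = aggregate_composition(otu, taxonomy, metadata,
                                             by = "season"))
    }
  })
  run_stage("diversity", {
    alpha <- alpha_diversity(otu)
    d <- bray_curtis(otu)
    site <- metadata$site[match(otu_samples(otu), metadata$sample_id)]
    season <- metadata$season[match(otu_samples(otu), metadata$sample_id)]
    list(alpha = alpha,
         nmds = nmds(d, seed = seed),
         permanova_site = permanova(d, site, n_perm = np, seed = seed),
         permanova_season = permanova(d, season, n_perm = np, seed = seed),
         anova_shannon_site = one_way_anova(alpha$shannon, site),
         anova_margalef_season = one_way_anova(alpha$margalef, season))
  })
  run_stage("env_anova", {
    list(by_site = env_anova(env, metadata, by = "site"),
         by_season = env_anova(env, metadata, by = "season"))
  })
  run_stage("decay", {
    d <- bray_curtis(otu)
    list(geographic = distance_decay(d, haversine_matrix(metadata),
                                     n_perm = np, seed = seed),
         environmental = distance_decay(d, env_distance(env),
                                        n_perm = np, seed = seed))
  })
  run_stage("mantel", {
    list(by_site = mantel_env_panel(otu, env, metadata, by = "site",
                                    n_perm = np, seed = seed),
         by_season = mantel_env_panel(otu, env, metadata, by = "season",
                                      n_perm = np, seed = seed))
  })
  run_stage("ordination", {
    dca <- dca_gradient_length(otu)
    out <- list(dca = dca)
    if (dca$model_choice == "linear") {
      fit <- rda_fit(otu, env)
      out$rda <- fit
      out$significance <- rda_significance(fit, "overall", n_perm = np,
                                           seed = seed)
      out$marginal <- rda_significance(fit, "margin", n_perm = np,
                                       seed = seed)
    } else {
      out$note <- "gradient length >= threshold; unimodal ordination recommended"
    }
    out
  })
  run_stage("network", {
    nets <- co_occurrence_networks(otu, metadata, by = "site")
    topo <- purrr::imap_dfr(nets, function(g, nm) {
      mutate(topology_metrics(g, seed = seed), group = nm) %>%
        select("group", dplyr::everything())
    })
    roles <- purrr::imap_dfr(nets, function(g, nm) {
      mutate(zi_pi(g, detect_modules(g, seed = seed)), group = nm)
    })
    list(networks = nets, topology = topo, roles = roles,
         key_species = roles %>% filter(.data$role != "peripheral"))
  })
  run_stage("tli", {
    scores <- tli_score(env, metadata, by = "site")
    alpha <- alpha_diversity(otu)
    per_sample <- tli_score(env, by = "sample")
    reg_env <- tli_regressions(
      per_sample$tli,
      env[match(per_sample$sample_id, env$sample_id), env_variables(env)])
    reg_div <- tli_regressions(
      per_sample$tli,
      alpha[match(per_sample$sample_id, alpha$sample_id),
            c("shannon", "margalef")])
    list(by_site = scores, per_sample = per_sample,
         regressions_env = reg_env, regressions_diversity = reg_div)
  })
  run_stage("assembly", {
    list(pooled_ncm = suppressWarnings(fit_ncm(otu)),
         pooled_mst = suppressWarnings(
           mst(otu, n_iter = cfg$null_iters, seed = seed)),
         by_site = assembly_by_group(otu, metadata, by = "site",
                                     n_iter = cfg$null_iters, seed = seed))
  })

  structure(list(results = results, errors = errors, config = cfg,
                 stages_run = names(results)),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report:", length(x$results), "stage bundle(s):",
      paste(names(x$results), collapse = ", "), "\n")
  if (length(x$errors) > 0) {
    cat("Stage error(s):\n")
    for (nm in names(x$errors)) cat(" -", nm, ":", x$errors[[nm]], "\n")
  }
  invisible(x)
}
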