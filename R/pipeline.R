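#' Pipeline configuration
#'
#' Bundles every choice the end-to-end pipeline needs: either file paths to
#' a panel and covariate CSV or a synthetic scenario, the model variant and
#' MCMC settings, the projection grid and target, and inequality options.
#' The seed is mandatory and drives every stochastic stage.
#'
#' @param output_dir Directory for stage outputs (created if needed).
#' @param seed Integer seed.
#' @param panel_path,covariates_path CSV inputs (dialects of [read_panel()]
#'   and [read_covariates()]); leave `NULL` to simulate instead.
#' @param scenario A [scenario_config()] used when no paths are given.
#' @param truth A [true_parameters()] for the simulated case.
#' @param variant Model variant (see [fit_cci_model()]).
#' @param candidate_covariates Covariates entering the VIF screen.
#' @param prior,half_cauchy_scale,chains,iter,burn,thin MCMC settings.
#' @param years Projection reporting grid.
#' @param target,threshold Coverage target (%) and on-track probability.
#' @param aggregate_method Regional aggregation (`"re_meta"` or
#'   `"weighted_mean"`).
#' @param region_weights Country weights for `"weighted_mean"`.
#' @param covariate_options Extra arguments for [simulate_covariates()] in
#'   the simulated case (e.g. `list(add_collinear = TRUE)`).
#' @return List of class `cci_pipeline_config`.
#' @export
pipeline_config <- function(output_dir,
                            seed = 1L,
                            panel_path = NULL,
                            covariates_path = NULL,
                            scenario = scenario_config(seed = seed),
                            truth = true_parameters(),
                            variant = "residence",
                            candidate_covariates = c("sdi", "ggdph", "gdpc"),
                            prior = "gamma",
                            half_cauchy_scale = 25,
                            chains = 4, iter = 2000, burn = iter %/% 2, thin = 1,
                            years = seq(2000, 2030, by = 5),
                            target = 80, threshold = 0.70,
                            aggregate_method = "re_meta",
                            region_weights = NULL,
                            covariate_options = list()) {
  structure(
    list(
      output_dir = output_dir, seed = as.integer(seed),
      panel_path = panel_path, covariates_path = covariates_path,
      scenario = scenario, truth = truth,
      variant = variant, candidate_covariates = candidate_covariates,
      prior = prior, half_cauchy_scale = half_cauchy_scale,
      chains = chains, iter = iter, burn = burn, thin = thin,
      years = years, target = target, threshold = threshold,
      aggregate_method = aggregate_method, region_weights = region_weights,
      covariate_options = covariate_options
    ),
    class = "cci_pipeline_config"
  )
}

#' Run the full coverage-monitoring pipeline
#'
#' Stages, in order: obtain data (read CSVs or simulate a synthetic
#' bundle), VIF-screen the candidate covariates, fit the hierarchical
#' model, compute diagnostics (PSRF, DIC, posterior predictive check),
#' project country trajectories, aggregate to regions, and build the
#' inequality table. All intermediates are written as CSV to the output
#' directory; a JSON run manifest records configuration, seeds, row
#' counts, retained covariates, timings and any diagnostic flags.
#' Identical configuration and seed give byte-identical output CSVs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest (list), invisibly; stage outputs are on disk and
#'   also attached as attribute `"results"`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cci_pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  timings <- list()
  flags <- character(0)
  stage <- function(name, expr) {
    ts <- Sys.time()
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        call. = FALSE
      )
    })
    timings[[name]] <<- round(as.numeric(Sys.time() - ts, units = "secs"), 3)
    out
  }

  data <- stage("data", {
    if (!is.null(config$panel_path)) {
      panel <- read_panel(config$panel_path)
      panel <- dplyr::filter(panel, .data$stratum_type == config$variant)
      covariates <- read_covariates(config$covariates_path)
      list(panel = panel, covariates = covariates)
    } else {
      bundle <- do.call(simulate_bundle, c(
        list(
          config = config$scenario, truth = config$truth,
          stratum_type = config$variant
        ),
        config$covariate_options
      ))
      list(panel = bundle$panel, covariates = bundle$covariates, bundle = bundle)
    }
  })

  vif <- stage("vif_screen", {
    if (length(config$candidate_covariates) >= 2) {
      vif_screen(data$covariates, config$candidate_covariates)
    } else {
      NULL
    }
  })
  retained <- if (is.null(vif)) config$candidate_covariates else vif$retained

  fit <- stage("fit", {
    withCallingHandlers(
      fit_cci_model(
        data$panel, data$covariates,
        variant = config$variant,
        covariate_names = retained,
        prior = config$prior, half_cauchy_scale = config$half_cauchy_scale,
        chains = config$chains, iter = config$iter, burn = config$burn,
        thin = config$thin, seed = config$seed
      ),
      warning = function(w) {
        flags <<- c(flags, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  })

  diag <- stage("diagnostics", {
    ppc <- posterior_predictive_check(fit, seed = config$seed + 7L)
    if (ppc$p_value < 0.05 || ppc$p_value > 0.95) {
      flags <<- c(flags, sprintf("extreme PPC p-value %.3f", ppc$p_value))
    }
    list(dic = compute_dic(fit), ppc = ppc, psrf = fit$convergence)
  })

  projection <- stage("projection", {
    predict_cci(fit, data$covariates,
      years = config$years,
      target = config$target, threshold = config$threshold
    )
  })

  regional <- stage("aggregate", {
    aggregate_region(projection,
      method = config$aggregate_method,
      weights = config$region_weights
    )
  })

  ineq <- stage("inequality", {
    if (config$variant == "national") NULL else inequality_table(projection)
  })

  stage("write", {
    readr::write_csv(
      dplyr::select(tibble::as_tibble(projection), -dplyr::any_of("weights")),
      file.path(config$output_dir, "projections.csv")
    )
    readr::write_csv(
      dplyr::select(tibble::as_tibble(regional), -dplyr::any_of("weights")),
      file.path(config$output_dir, "regions.csv")
    )
    if (!is.null(ineq)) {
      readr::write_csv(ineq, file.path(config$output_dir, "inequality.csv"))
    }
    if (!is.null(vif)) {
      readr::write_csv(vif$rounds, file.path(config$output_dir, "vif_rounds.csv"))
    }
    readr::write_csv(
      dplyr::left_join(
        fit$convergence,
        tibble::tibble(
          parameter = names(colMeans(as_draws_matrix(fit))),
          posterior_mean = unname(colMeans(as_draws_matrix(fit)))
        ),
        by = "parameter"
      ),
      file.path(config$output_dir, "parameters.csv")
    )
    NULL
  })

  config_for_hash <- config
  config_for_hash$output_dir <- NULL
  manifest <- list(
    package_version = as.character(utils::packageVersion("ccitrend")),
    config_hash = rlang::hash(config_for_hash),
    seed = config$seed,
    variant = config$variant,
    n_panel_rows = nrow(data$panel),
    n_covariate_rows = nrow(data$covariates),
    candidate_covariates = config$candidate_covariates,
    retained_covariates = retained,
    eliminated_covariates = if (is.null(vif)) character(0) else vif$eliminated,
    reference_level = fit$design$reference_level,
    aggregate_method = config$aggregate_method,
    dic = diag$dic$dic, p_d = diag$dic$p_d,
    ppc_p_value = diag$ppc$p_value,
    max_fixed_psrf = max(
      diag$psrf$psrf[diag$psrf$parameter %in% fit$fixed_names],
      na.rm = TRUE
    ),
    convergence_ok = fit$convergence_ok,
    flags = flags,
    stage_seconds = timings,
    total_seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 3)
  )
  jsonlite::write_json(manifest, file.path(config$output_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  attr(manifest, "results") <- list(
    fit = fit, projection = projection, regional = regional,
    inequality = ineq, vif = vif, diagnostics = diag, data = data
  )
  invisible(manifest)
}
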