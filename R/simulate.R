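#' Scenario configuration for the synthetic survey-panel generator
#'
#' Describes a multi-country monitoring scenario: a region/country hierarchy,
#' an observed survey window inside a longer projection window, a survey
#' sparsity pattern (including countries contributing a single data point, a
#' common situation in LMIC coverage monitoring), and the logit-scale
#' residual noise of observed stratum-level CCI values.
#'
#' @param n_regions Number of regions (default 9, the UN regional grouping
#'   size used for LMIC monitoring).
#' @param countries_per_region Scalar or length-`n_regions` vector of country
#'   counts. The default `c(8, 8, 8, 8, 8, 8, 8, 7, 7)` gives 70 countries.
#' @param observed_years Two-element year range within which surveys occur
#'   (default 2000-2020).
#' @param projection_years Two-element year range the latent surface and
#'   covariates must cover (default 2000-2030).
#' @param surveys_min,surveys_max Range of survey counts per country
#'   (uniform; default 1-8).
#' @param single_survey_fraction Fraction of countries forced to exactly one
#'   survey (default 20/70, the observed sparsity in multi-country CCI
#'   panels).
#' @param noise_sd_logit Logit-scale SD of observation noise around the
#'   latent CCI surface (default 0.1).
#' @param seed Integer seed; mandatory, drives all generator randomness.
#'
#' @return A list of class `cci_scenario`.
#' @export
scenario_config <- function(n_regions = 9,
                            countries_per_region = c(8, 8, 8, 8, 8, 8, 8, 7, 7),
                            observed_years = c(2000, 2020),
                            projection_years = c(2000, 2030),
                            surveys_min = 1,
                            surveys_max = 8,
                            single_survey_fraction = 20 / 70,
                            noise_sd_logit = 0.1,
                            seed = 1L) {
  if (n_regions < 1) stop("n_regions must be >= 1", call. = FALSE)
  if (length(countries_per_region) == 1) {
    countries_per_region <- rep(countries_per_region, n_regions)
  }
  if (length(countries_per_region) != n_regions) {
    stop("countries_per_region must be a scalar or length n_regions", call. = FALSE)
  }
  if (any(countries_per_region < 1)) {
    stop("countries_per_region entries must be positive", call. = FALSE)
  }
  if (observed_years[1] < projection_years[1] ||
    observed_years[2] > projection_years[2]) {
    stop("observed_years must lie within projection_years", call. = FALSE)
  }
  if (surveys_min < 1 || surveys_max < surveys_min) {
    stop("need 1 <= surveys_min <= surveys_max", call. = FALSE)
  }
  if (!is.numeric(noise_sd_logit) || noise_sd_logit <= 0) {
    stop("noise_sd_logit must be > 0", call. = FALSE)
  }
  if (single_survey_fraction < 0 || single_survey_fraction > 1) {
    stop("single_survey_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_regions = as.integer(n_regions),
      countries_per_region = as.integer(countries_per_region),
      observed_years = as.integer(observed_years),
      projection_years = as.integer(projection_years),
      surveys_min = as.integer(surveys_min),
      surveys_max = as.integer(surveys_max),
      single_survey_fraction = single_survey_fraction,
      noise_sd_logit = noise_sd_logit,
      seed = as.integer(seed)
    ),
    class = "cci_scenario"
  )
}

#' Ground-truth parameters for the synthetic generator
#'
#' The generator runs the hierarchical coverage model forwards: logit-CCI is
#' a linear predictor with a global intercept, region and country random
#' intercepts, a per-decade time trend, stratum offsets and standardised
#' country-year covariate effects. Defaults encode the qualitative gradients
#' seen in RMNCH coverage data: urban above rural, coverage non-decreasing
#' across wealth quintiles and education levels, and a positive secular
#' trend.
#'
#' @param global_intercept Logit-scale global mean (default 0.3, about 57%
#'   coverage at the 2015 covariate centre).
#' @param region_intercept_sd,country_intercept_sd SDs of region and country
#'   random intercepts (defaults 0.3 and 0.4 logit units).
#' @param beta_year Trend per decade on the logit scale (default 0.3).
#' @param beta_residence Named offsets for `national`, `urban`, `rural`
#'   (national is the reference, 0).
#' @param beta_wealth Named offsets for quintiles `Q1`-`Q5`, non-decreasing
#'   by default (Q1 = lowest income is the reference).
#' @param beta_education Named offsets for `none`, `primary`,
#'   `secondary_plus` (none is the reference).
#' @param beta_sdi,beta_ggdph,beta_gdpc Effects of the standardised
#'   sociodemographic index, government health spending share, and GDP per
#'   capita.
#'
#' @return A list of class `cci_truth`.
#' @export
true_parameters <- function(global_intercept = 0.3,
                            region_intercept_sd = 0.3,
                            country_intercept_sd = 0.4,
                            beta_year = 0.3,
                            beta_residence = c(national = 0, urban = 0.4, rural = -0.3),
                            beta_wealth = c(Q1 = 0, Q2 = 0.2, Q3 = 0.4, Q4 = 0.6, Q5 = 0.9),
                            beta_education = c(none = 0, primary = 0.3, secondary_plus = 0.7),
                            beta_sdi = 1.0,
                            beta_ggdph = 0.05,
                            beta_gdpc = 0.2) {
  vals <- c(
    global_intercept, region_intercept_sd, country_intercept_sd, beta_year,
    beta_residence, beta_wealth, beta_education, beta_sdi, beta_ggdph, beta_gdpc
  )
  if (!all(is.finite(vals))) stop("all true parameters must be finite", call. = FALSE)
  if (region_intercept_sd <= 0 || country_intercept_sd <= 0) {
    stop("hierarchy SDs must be positive", call. = FALSE)
  }
  if (is.unsorted(beta_wealth)) {
    stop("default contract: beta_wealth must be non-decreasing Q1 -> Q5", call. = FALSE)
  }
  if (beta_residence[["urban"]] < beta_residence[["rural"]]) {
    stop("default contract: urban offset must be >= rural offset", call. = FALSE)
  }
  structure(
    list(
      global_intercept = global_intercept,
      region_intercept_sd = region_intercept_sd,
      country_intercept_sd = country_intercept_sd,
      beta_year = beta_year,
      beta_residence = beta_residence,
      beta_wealth = beta_wealth,
      beta_education = beta_education,
      beta_sdi = beta_sdi,
      beta_ggdph = beta_ggdph,
      beta_gdpc = beta_gdpc
    ),
    class = "cci_truth"
  )
}

stratum_levels_for <- function(stratum_type) {
  switch(stratum_type,
    national = "national",
    residence = c("national", "urban", "rural"),
    wealth = c("Q1", "Q2", "Q3", "Q4", "Q5"),
    education = c("none", "primary", "secondary_plus"),
    stop(sprintf("unknown stratum type '%s'", stratum_type), call. = FALSE)
  )
}

stratum_offsets_for <- function(truth, stratum_type) {
  offs <- switch(stratum_type,
    national = c(national = 0),
    residence = truth$beta_residence,
    wealth = truth$beta_wealth,
    education = truth$beta_education
  )
  levels <- stratum_levels_for(stratum_type)
  missing <- setdiff(levels, names(offs))
  if (length(missing) > 0) {
    stop(sprintf(
      "true parameters missing stratum offset(s): %s",
      paste(missing, collapse = ", ")
    ), call. = FALSE)
  }
  offs[levels]
}

#' Generate the region/country hierarchy of a scenario
#'
#' Assignment is deterministic: countries `C001, C002, ...` are allocated to
#' regions `R1, R2, ...` in blocks of `countries_per_region`.
#'
#' @param config A [scenario_config()].
#' @return Tibble with columns `country_id`, `region_id`.
#' @export
simulate_hierarchy <- function(config) {
  stopifnot(inherits(config, "cci_scenario"))
  n <- sum(config$countries_per_region)
  tibble::tibble(
    country_id = sprintf("C%03d", seq_len(n)),
    region_id = rep(
      sprintf("R%d", seq_len(config$n_regions)),
      times = config$countries_per_region
    )
  )
}

#' Generate country-year covariate trajectories through the projection range
#'
#' One row per country-year over the projection window. The sociodemographic
#' index (SDI) follows country-specific logistic growth (in (0,1),
#' non-decreasing), GDP per capita (GDPC) grows log-linearly, and government
#' health spending share of GDP (GGDPH) follows a stationary AR(1) around a
#' country-level mean, kept inside (0, 20)%.
#'
#' @param hierarchy Output of [simulate_hierarchy()].
#' @param config A [scenario_config()].
#' @param add_collinear If `TRUE`, append `gdpc_copy`, an exact duplicate of
#'   `gdpc` — a constructed perfect-collinearity case for exercising the VIF
#'   screen.
#' @param include_optional If `TRUE`, append `dah` (development assistance
#'   for health) and `hrh` (human resources for health); `hrh` is generated
#'   strongly correlated with SDI so that multicollinearity screening has
#'   something to find.
#'
#' @return Tibble with columns `country_id`, `year`, `sdi`, `ggdph`, `gdpc`
#'   (plus optional columns).
#' @export
simulate_covariates <- function(hierarchy, config,
                                add_collinear = FALSE,
                                include_optional = FALSE) {
  stopifnot(nrow(hierarchy) > 0)
  years <- seq(config$projection_years[1], config$projection_years[2])
  withr::with_seed(config$seed + 1L, {
    per_country <- purrr::map(hierarchy$country_id, function(cid) {
      t0 <- years - 2000
      a <- stats::runif(1, -1.5, 0.5)
      b <- stats::runif(1, 0.02, 0.06)
      sdi <- stats::plogis(a + b * t0)
      g0 <- exp(stats::runif(1, log(500), log(8000)))
      r <- stats::runif(1, 0.005, 0.04)
      gdpc <- g0 * exp(r * t0)
      m <- stats::runif(1, 1, 6)
      phi <- 0.7
      eps <- stats::rnorm(length(years), 0, 0.15)
      gg <- numeric(length(years))
      gg[1] <- m + eps[1]
      for (i in seq_along(years)[-1]) {
        gg[i] <- m + phi * (gg[i - 1] - m) + eps[i]
      }
      gg <- pmin(pmax(gg, 0.2), 19.8)
      out <- tibble::tibble(
        country_id = cid, year = years,
        sdi = sdi, ggdph = gg, gdpc = gdpc
      )
      if (include_optional) {
        out$dah <- exp(stats::runif(1, log(5), log(80))) *
          exp(stats::rnorm(length(years), 0, 0.05))
        out$hrh <- 5 + 40 * sdi + stats::rnorm(length(years), 0, 0.5)
      }
      out
    })
    out <- dplyr::bind_rows(per_country)
  })
  if (add_collinear) out$gdpc_copy <- out$gdpc
  out
}

# Shared standardisation constants: both the generator and the model design
# z-score covariates against the full country x projection-year grid, so true
# and fitted coefficients live on the same scale.
covariate_scaling <- function(covariates, names) {
  list(
    mean = vapply(names, function(nm) mean(covariates[[nm]]), numeric(1)),
    sd = vapply(names, function(nm) stats::sd(covariates[[nm]]), numeric(1))
  )
}

scale_covariates <- function(covariates, names, scaling) {
  out <- covariates
  for (nm in names) {
    out[[nm]] <- (covariates[[nm]] - scaling$mean[[nm]]) / scaling$sd[[nm]]
  }
  out
}

#' Simulate a coverage panel with known ground truth
#'
#' Runs the hierarchical model generatively: a latent logit-CCI surface over
#' every country, projection year and stratum level is built from `truth`;
#' observations are the inverse-logit of the latent value plus
#' `Normal(0, noise_sd_logit)` noise at survey years sampled uniformly
#' without replacement within the observed window. A configurable fraction
#' of countries is forced to a single survey.
#'
#' @param hierarchy Output of [simulate_hierarchy()].
#' @param covariates Output of [simulate_covariates()]; must cover the
#'   projection range.
#' @param truth A [true_parameters()] object.
#' @param config A [scenario_config()].
#' @param stratum_type One of `"national"`, `"residence"`, `"wealth"`,
#'   `"education"`.
#'
#' @return A list of class `cci_bundle` with elements `panel` (observed
#'   rows: `country_id`, `region_id`, `year`, `stratum_type`,
#'   `stratum_level`, `cci`), `latent` (full true CCI grid, including a
#'   `cci_true` column), `covariates`, `truth`, `hierarchy`, `config`,
#'   `region_effects`, `country_effects`.
#' @export
simulate_panel <- function(hierarchy, covariates, truth, config,
                           stratum_type = "residence") {
  stopifnot(inherits(config, "cci_scenario"), inherits(truth, "cci_truth"))
  years_all <- seq(config$projection_years[1], config$projection_years[2])
  if (!all(years_all %in% covariates$year)) {
    stop("covariates must cover the full projection year range", call. = FALSE)
  }
  offsets <- stratum_offsets_for(truth, stratum_type)
  levels <- names(offsets)
  core <- c("sdi", "ggdph", "gdpc")
  scaling <- covariate_scaling(covariates, core)
  cov_z <- scale_covariates(covariates, core, scaling)

  withr::with_seed(config$seed + 2L, {
    u_region <- stats::rnorm(config$n_regions, 0, truth$region_intercept_sd)
    names(u_region) <- sprintf("R%d", seq_len(config$n_regions))
    u_country <- stats::rnorm(nrow(hierarchy), 0, truth$country_intercept_sd)
    names(u_country) <- hierarchy$country_id

    latent <- tidyr::expand_grid(
      hierarchy,
      year = years_all,
      stratum_level = levels
    ) |>
      dplyr::left_join(
        dplyr::select(cov_z, "country_id", "year", dplyr::all_of(core)),
        by = c("country_id", "year")
      ) |>
      dplyr::mutate(
        eta = truth$global_intercept +
          unname(u_region[.data$region_id]) +
          unname(u_country[.data$country_id]) +
          truth$beta_year * (.data$year - 2015) / 10 +
          unname(offsets[.data$stratum_level]) +
          truth$beta_sdi * .data$sdi +
          truth$beta_ggdph * .data$ggdph +
          truth$beta_gdpc * .data$gdpc,
        cci_true = inv_logit(.data$eta),
        stratum_type = stratum_type
      ) |>
      dplyr::select(
        "country_id", "region_id", "year", "stratum_type",
        "stratum_level", "cci_true"
      )

    n_c <- nrow(hierarchy)
    n_single <- round(config$single_survey_fraction * n_c)
    single <- sample(hierarchy$country_id, n_single)
    obs_years <- seq(config$observed_years[1], config$observed_years[2])
    survey_years <- purrr::map(hierarchy$country_id, function(cid) {
      counts <- seq(config$surveys_min, config$surveys_max)
      n_s <- if (cid %in% single) {
        1L
      } else if (length(counts) == 1) {
        counts # sample() would misread a length-1 vector as 1:n
      } else {
        sample(counts, 1)
      }
      sort(sample(obs_years, min(n_s, length(obs_years))))
    })
    names(survey_years) <- hierarchy$country_id

    panel <- latent |>
      dplyr::filter(purrr::map2_lgl(
        .data$country_id, .data$year,
        function(cid, yr) yr %in% survey_years[[cid]]
      )) |>
      dplyr::mutate(
        cci = inv_logit(
          logit(.data$cci_true, eps = 1e-9) +
            stats::rnorm(dplyr::n(), 0, config$noise_sd_logit)
        )
      ) |>
      dplyr::select(
        "country_id", "region_id", "year", "stratum_type",
        "stratum_level", "cci"
      )
  })

  structure(
    list(
      panel = panel, latent = latent, covariates = covariates,
      truth = truth, hierarchy = hierarchy, config = config,
      stratum_type = stratum_type,
      region_effects = u_region, country_effects = u_country
    ),
    class = "cci_bundle"
  )
}

#' Simulate a complete synthetic bundle in one call
#'
#' @inheritParams simulate_panel
#' @param config A [scenario_config()].
#' @param truth A [true_parameters()] object.
#' @param ... Passed to [simulate_covariates()].
#' @return A `cci_bundle`; see [simulate_panel()].
#' @export
simulate_bundle <- function(config = scenario_config(),
                            truth = true_parameters(),
                            stratum_type = "residence", ...) {
  hierarchy <- simulate_hierarchy(config)
  covariates <- simulate_covariates(hierarchy, config, ...)
  simulate_panel(hierarchy, covariates, truth, config, stratum_type)
}

#' Decompose a CCI value into eight consistent indicator proportions
#'
#' Produces, for each target CCI, a random indicator set whose weighted
#' average (per [cci_weights()]) equals the target exactly: a random
#' direction in the null space of the weight vector is added to the constant
#' solution and scaled to stay inside the unit box. This lets the composite
#' index be exercised end-to-end against a known answer.
#'
#' @param cci Numeric vector of target CCI proportions in \[0, 1\].
#' @param seed Integer seed.
#' @return Tibble with the eight indicator columns and a `cci_target`
#'   column; `batch_cci()` on the indicators reproduces `cci_target` to
#'   within 1e-9.
#' @export
derive_indicator_components <- function(cci, seed = 1L) {
  if (any(!is.finite(cci) | cci < 0 | cci > 1)) {
    stop("target CCI values must lie in [0, 1]", call. = FALSE)
  }
  w <- cci_weights()
  withr::with_seed(seed, {
    rows <- purrr::map(cci, function(target) {
      z <- stats::rnorm(8)
      d <- z - w * sum(w * z) / sum(w * w)
      step <- ifelse(d > 0, (1 - target) / d, ifelse(d < 0, -target / d, Inf))
      s_max <- min(step)
      x <- target + stats::runif(1, 0, 0.95) * s_max * d
      x <- pmin(pmax(x, 0), 1)
      stats::setNames(as.list(x), names(w))
    })
  })
  out <- dplyr::bind_rows(rows)
  out$cci_target <- cci
  out
}

#' Write a synthetic bundle to disk in the package's CSV/YAML dialect
#'
#' The panel is written in the long dialect that [read_panel()] accepts
#' (`iso3, region, year, stratifier, level, value, scale`), covariates as a
#' plain country-year CSV, and the ground-truth parameters as YAML so that
#' recovery experiments can reload them.
#'
#' @param bundle A `cci_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cci_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  panel_out <- tibble::tibble(
    iso3 = bundle$panel$country_id,
    region = bundle$panel$region_id,
    year = bundle$panel$year,
    stratifier = bundle$panel$stratum_type,
    level = bundle$panel$stratum_level,
    value = bundle$panel$cci,
    scale = "proportion"
  )
  readr::write_csv(panel_out, file.path(dir, "panel.csv"))
  readr::write_csv(bundle$covariates, file.path(dir, "covariates.csv"))
  truth <- bundle$truth
  yaml::write_yaml(
    lapply(unclass(truth), function(x) if (is.numeric(x)) as.list(x) else x),
    file.path(dir, "truth.yaml")
  )
  invisible(dir)
}
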