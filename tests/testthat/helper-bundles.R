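# Small shared fixtures, built in code.

tiny_config <- function(seed = 11, ...) {
  scenario_config(
    n_regions = 3, countries_per_region = 3,
    surveys_min = 2, surveys_max = 4, single_survey_fraction = 0.2,
    seed = seed, ...
  )
}

tiny_bundle <- function(seed = 11, stratum_type = "residence", ...) {
  simulate_bundle(tiny_config(seed = seed), stratum_type = stratum_type, ...)
}

quick_fit <- function(bundle, chains = 2, iter = 800, burn = 400, seed = 3, ...) {
  suppressWarnings(fit_cci_model(
    bundle$panel, bundle$covariates,
    variant = bundle$stratum_type,
    chains = chains, iter = iter, burn = burn, seed = seed, ...
  ))
}

# One moderately sized fitted model reused across test files.
shared_fit_cache <- new.env(parent = emptyenv())

shared_fit <- function() {
  if (is.null(shared_fit_cache$fit)) {
    shared_fit_cache$bundle <- tiny_bundle(seed = 42)
    shared_fit_cache$fit <- quick_fit(shared_fit_cache$bundle,
      chains = 4, iter = 1500, burn = 500, seed = 7
    )
  }
  list(bundle = shared_fit_cache$bundle, fit = shared_fit_cache$fit)
}

random_indicator_row <- function() {
  stats::setNames(as.list(stats::runif(8)), names(cci_weights()))
}
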