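#' Build the hierarchical model design from a panel and covariate table
#'
#' Assembles, in a fixed deterministic order, the response (logit-CCI) and
#' the fixed-effect matrix: intercept, year centred at 2015 and scaled per
#' decade, stratum dummy variables against a declared reference level
#' (national for residence, Q1 for wealth, none for education), standardised
#' country-year covariates, and optionally residence-by-country interaction
#' dummies. Region and country random-intercept indices are returned
#' alongside, with levels that contain a single unit absorbed into the
#' intercept. Standardisation constants are computed from the full covariate
#' grid and returned for later prediction.
#'
#' @param panel Coverage panel tibble with columns `country_id`,
#'   `region_id`, `year`, `stratum_type`, `stratum_level`, `cci` (proportion
#'   scale).
#' @param covariates Country-year covariate tibble covering every panel row
#'   (and the projection years used later).
#' @param variant Stratification variant: `"national"`, `"residence"`,
#'   `"wealth"` or `"education"`. Panel rows with other `stratum_type`s are
#'   rejected.
#' @param covariate_names Ordered character vector of covariate columns to
#'   include (default `c("sdi", "ggdph", "gdpc")`, the post-screening set).
#' @param interactions Include residence-by-country interaction dummies
#'   (only meaningful for the residence variant; default `FALSE`).
#' @param eps Clipping bound for the logit transform.
#'
#' @return A list of class `cci_design`: `y`, `X`, `region_idx`,
#'   `country_idx`, `region_levels`, `country_levels`, `country_region` (map
#'   country -> region), `scaling`, `stratum_levels`, `reference_level`,
#'   `variant`, `covariate_names`, `interactions`.
#' @export
build_design <- function(panel, covariates, variant = "residence",
                         covariate_names = c("sdi", "ggdph", "gdpc"),
                         interactions = FALSE, eps = 1e-3) {
  variant <- match.arg(variant, c("national", "residence", "wealth", "education"))
  panel <- dplyr::arrange(
    tibble::as_tibble(panel),
    .data$country_id, .data$year, .data$stratum_level
  )
  if (nrow(panel) == 0) stop("panel is empty", call. = FALSE)
  if (!all(panel$stratum_type == variant)) {
    stop(sprintf(
      "panel contains stratum_type other than '%s'; filter before fitting",
      variant
    ), call. = FALSE)
  }
  missing_cov <- dplyr::anti_join(
    dplyr::distinct(panel, .data$country_id, .data$year),
    covariates,
    by = c("country_id", "year")
  )
  if (nrow(missing_cov) > 0) {
    gaps <- paste(sprintf(
      "(%s, %d)", missing_cov$country_id, missing_cov$year
    ), collapse = ", ")
    stop(sprintf("no covariate rows for: %s", gaps), call. = FALSE)
  }
  bad_cov <- setdiff(covariate_names, names(covariates))
  if (length(bad_cov) > 0) {
    stop(sprintf(
      "covariate table lacks column(s): %s",
      paste(bad_cov, collapse = ", ")
    ), call. = FALSE)
  }

  levels_all <- stratum_levels_for(variant)
  bad_lvl <- setdiff(unique(panel$stratum_level), levels_all)
  if (length(bad_lvl) > 0) {
    stop(sprintf(
      "unknown stratum level(s) for variant '%s': %s", variant,
      paste(bad_lvl, collapse = ", ")
    ), call. = FALSE)
  }
  reference <- levels_all[1]

  scaling <- covariate_scaling(covariates, covariate_names)
  cov_z <- scale_covariates(covariates, covariate_names, scaling)
  rows <- dplyr::left_join(
    panel,
    dplyr::select(cov_z, "country_id", "year", dplyr::all_of(covariate_names)),
    by = c("country_id", "year")
  )

  n <- nrow(rows)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- cbind(X, year = (rows$year - 2015) / 10)
  present_levels <- levels_all[levels_all %in% unique(rows$stratum_level)]
  for (lvl in setdiff(present_levels, reference)) {
    col <- as.numeric(rows$stratum_level == lvl)
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- paste0(variant, "_", lvl)
  }
  for (nm in covariate_names) {
    X <- cbind(X, rows[[nm]])
    colnames(X)[ncol(X)] <- nm
  }

  country_levels <- sort(unique(rows$country_id))
  region_levels <- sort(unique(rows$region_id))
  if (interactions && variant == "residence" && length(country_levels) > 1) {
    for (lvl in setdiff(present_levels, reference)) {
      for (cid in country_levels[-1]) {
        col <- as.numeric(rows$stratum_level == lvl & rows$country_id == cid)
        X <- cbind(X, col)
        colnames(X)[ncol(X)] <- paste0(variant, "_", lvl, ":", cid)
      }
    }
  }

  if (qr(X, tol = 1e-10)$rank < ncol(X)) {
    stop(paste(
      "design matrix is rank-deficient (collinear columns);",
      "run vif_screen() on the candidate covariates first"
    ), call. = FALSE)
  }

  use_region <- length(region_levels) > 1
  use_country <- length(country_levels) > 1
  cr <- dplyr::distinct(rows, .data$country_id, .data$region_id)
  if (any(duplicated(cr$country_id))) {
    stop("a country maps to more than one region", call. = FALSE)
  }
  country_region <- stats::setNames(cr$region_id, cr$country_id)[country_levels]

  structure(
    list(
      y = logit(rows$cci, eps = eps),
      X = X,
      rows = dplyr::select(
        rows, "country_id", "region_id", "year",
        "stratum_level", "cci"
      ),
      region_idx = if (use_region) match(rows$region_id, region_levels) else NULL,
      country_idx = if (use_country) match(rows$country_id, country_levels) else NULL,
      region_levels = region_levels,
      country_levels = country_levels,
      country_region = country_region,
      use_region = use_region,
      use_country = use_country,
      scaling = scaling,
      stratum_levels = present_levels,
      reference_level = reference,
      variant = variant,
      covariate_names = covariate_names,
      interactions = interactions,
      eps = eps
    ),
    class = "cci_design"
  )
}
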