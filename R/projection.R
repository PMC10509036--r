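#' Project country-level CCI trajectories from a fitted model
#'
#' For every requested country, stratum level and year, the linear predictor
#' is evaluated at each posterior draw (using the standardisation constants
#' stored in the design), mapped through the inverse logit, and summarised
#' by the posterior mean and central 95% credible interval, on the
#' percentage scale. The probability of reaching the coverage target (80%
#' by default, the UHC operational target) is the fraction of draws at or
#' above it; a unit is classified on track when that probability is at
#' least `threshold` (0.70 by default).
#'
#' @param fit A `cci_fit`.
#' @param covariates Country-year covariate table covering every requested
#'   year (the same table used at fit time, which extends through 2030).
#' @param years Years to project (default the reporting grid 2000-2030 in
#'   5-year steps).
#' @param strata Stratum levels to project (default: all levels present in
#'   the fit, including the reference).
#' @param countries Countries (default: all in the fit).
#' @param target Coverage target in % (default 80).
#' @param threshold On-track probability threshold (default 0.70).
#'
#' @return A tibble of class `cci_projection`: `unit`, `unit_type`
#'   (`"country"`), `region`, `stratum_level`, `year`, `mean`, `cri_low`,
#'   `cri_high` (all in %), `p_target`, `on_track`. The per-draw CCI grid
#'   (draws x rows, % scale) is attached as attribute `"draws"`.
#' @export
predict_cci <- function(fit, covariates,
                        years = seq(2000, 2030, by = 5),
                        strata = NULL, countries = NULL,
                        target = 80, threshold = 0.70) {
  stopifnot(inherits(fit, "cci_fit"))
  design <- fit$design
  strata <- strata %||% design$stratum_levels
  countries <- countries %||% design$country_levels
  bad <- setdiff(strata, design$stratum_levels)
  if (length(bad) > 0) {
    stop(sprintf(
      "stratum level(s) not in the fitted model: %s",
      paste(bad, collapse = ", ")
    ), call. = FALSE)
  }
  grid <- tidyr::expand_grid(
    unit = countries, stratum_level = strata, year = years
  )
  cov_need <- dplyr::distinct(grid, country_id = .data$unit, .data$year)
  cov_rows <- dplyr::inner_join(covariates, cov_need, by = c("country_id", "year"))
  if (nrow(cov_rows) < nrow(cov_need)) {
    miss <- dplyr::anti_join(cov_need, covariates, by = c("country_id", "year"))
    stop(sprintf(
      "covariates missing for %d country-years (first: %s, %d)",
      nrow(miss), miss$country_id[1], miss$year[1]
    ), call. = FALSE)
  }
  cov_z <- scale_covariates(cov_rows, design$covariate_names, design$scaling)
  grid <- dplyr::left_join(
    grid,
    dplyr::select(
      cov_z, unit = "country_id", "year",
      dplyr::all_of(design$covariate_names)
    ),
    by = c("unit", "year")
  )

  Xp <- matrix(0, nrow(grid), length(fit$fixed_names),
    dimnames = list(NULL, fit$fixed_names)
  )
  Xp[, "(Intercept)"] <- 1
  Xp[, "year"] <- (grid$year - 2015) / 10
  for (lvl in setdiff(design$stratum_levels, design$reference_level)) {
    col <- paste0(design$variant, "_", lvl)
    if (col %in% colnames(Xp)) Xp[, col] <- as.numeric(grid$stratum_level == lvl)
  }
  for (nm in design$covariate_names) Xp[, nm] <- grid[[nm]]
  if (design$interactions) {
    for (cn in grep(":", fit$fixed_names, value = TRUE)) {
      parts <- strsplit(cn, ":", fixed = TRUE)[[1]]
      lvl <- sub(paste0("^", design$variant, "_"), "", parts[1])
      Xp[, cn] <- as.numeric(grid$stratum_level == lvl & grid$unit == parts[2])
    }
  }
  region_of <- design$country_region[grid$unit]
  region_idx <- if (design$use_region) match(region_of, design$region_levels)
  country_idx <- if (design$use_country) match(grid$unit, design$country_levels)

  eta <- linpred_draws(fit, Xp, region_idx, country_idx)
  cci_draws <- 100 * inv_logit(eta)

  qs <- apply(cci_draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- tibble::tibble(
    unit = grid$unit,
    unit_type = "country",
    region = unname(region_of),
    stratum_level = grid$stratum_level,
    year = grid$year,
    mean = colMeans(cci_draws),
    cri_low = qs[1, ],
    cri_high = qs[2, ],
    p_target = colMeans(cci_draws >= target)
  )
  out$on_track <- out$p_target >= threshold
  structure(out,
    class = c("cci_projection", class(out)),
    draws = cci_draws, target = target, threshold = threshold
  )
}

#' Probability of reaching a coverage target from posterior draws
#'
#' @param draws Numeric vector of posterior CCI draws (% scale) for one
#'   unit-year.
#' @param target Target coverage in % (default 80).
#' @param threshold On-track probability threshold (default 0.70).
#' @return One-row tibble: `p_target`, `on_track`.
#' @export
#' @examples
#' prob_target(c(85, 90, 79, 88), target = 80)
prob_target <- function(draws, target = 80, threshold = 0.70) {
  if (length(draws) < 1) stop("no draws supplied", call. = FALSE)
  p <- mean(draws >= target)
  tibble::tibble(p_target = p, on_track = p >= threshold)
}

#' DerSimonian-Laird random-effects pooling
#'
#' Method-of-moments random-effects combination of `k` estimates with
#' within-study variances: Q is the fixed-effect heterogeneity statistic,
#' `tau2 = max(0, (Q - (k-1)) / c)` with
#' `c = sum(w) - sum(w^2)/sum(w)` and `w = 1/vi`, and the pooled estimate
#' uses weights `1/(vi + tau2)`.
#'
#' @param yi Numeric vector of estimates (here: country logit-CCI values).
#' @param vi Within-study variances, same length.
#' @return One-row tibble: `estimate`, `se`, `tau2`, `q`, plus list-column
#'   `weights` (normalised random-effects weights).
#' @export
dl_pool <- function(yi, vi) {
  k <- length(yi)
  stopifnot(length(vi) == k, all(vi > 0))
  if (k == 1) {
    return(tibble::tibble(
      estimate = yi, se = sqrt(vi), tau2 = 0, q = 0, weights = list(1)
    ))
  }
  w <- 1 / vi
  ybar_f <- sum(w * yi) / sum(w)
  q <- sum(w * (yi - ybar_f)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (q - (k - 1)) / cc)
  w_re <- 1 / (vi + tau2)
  est <- sum(w_re * yi) / sum(w_re)
  tibble::tibble(
    estimate = est,
    se = sqrt(1 / sum(w_re)),
    tau2 = tau2,
    q = q,
    weights = list(w_re / sum(w_re))
  )
}

# Vectorised DL pooling across posterior draws: yi is draws x k (logit
# scale), vi a length-k vector of per-country posterior variances held
# fixed across draws. Returns list(pooled = vector over draws, tau2 = ...).
dl_pool_draws <- function(yi, vi) {
  k <- ncol(yi)
  if (k == 1) {
    return(list(pooled = as.numeric(yi[, 1]), tau2 = rep(0, nrow(yi))))
  }
  w <- 1 / vi
  sw <- sum(w)
  ybar <- as.numeric(yi %*% w) / sw
  q <- as.numeric((yi^2) %*% w) - 2 * ybar * as.numeric(yi %*% w) + ybar^2 * sw
  cc <- sw - sum(w^2) / sw
  tau2 <- pmax(0, (q - (k - 1)) / cc)
  W <- 1 / outer(tau2, vi, "+")
  pooled <- rowSums(W * yi) / rowSums(W)
  list(pooled = pooled, tau2 = tau2)
}

#' Aggregate country projections to regional trajectories
#'
#' Aggregation is done per posterior draw on the logit scale (so results
#' stay inside 0-100%), then back-transformed and summarised over draws.
#' With `method = "re_meta"` (default) each draw's country values are
#' combined by DerSimonian-Laird random-effects pooling, using the
#' across-draw posterior variance of each country's logit-CCI as its
#' within-country variance; with `method = "weighted_mean"` a fixed weighted
#' average (e.g. population weights) is taken per draw. Single-country
#' regions return the country projection unchanged.
#'
#' @param projection A `cci_projection` from [predict_cci()] (with draws
#'   attached).
#' @param method `"re_meta"` or `"weighted_mean"`.
#' @param weights Named numeric vector of country weights (required for
#'   `"weighted_mean"`; e.g. population).
#' @param target,threshold Target coverage (%) and on-track probability
#'   threshold; default to those stored in `projection`.
#' @return Tibble of class `cci_regional`: `unit` (region), `unit_type`
#'   (`"region"`), `stratum_level`, `year`, `mean`, `cri_low`, `cri_high`,
#'   `p_target`, `on_track`, `het_sd` (between-country heterogeneity SD on
#'   the logit scale; 0 for weighted means), `n_countries`, `method`.
#'   Per-draw regional CCI (% scale) attached as attribute `"draws"`.
#' @export
aggregate_region <- function(projection, method = c("re_meta", "weighted_mean"),
                             weights = NULL, target = NULL, threshold = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(projection, "cci_projection"))
  draws <- attr(projection, "draws")
  if (is.null(draws)) stop("projection carries no draws attribute", call. = FALSE)
  target <- target %||% attr(projection, "target") %||% 80
  threshold <- threshold %||% attr(projection, "threshold") %||% 0.70
  if (method == "weighted_mean" && is.null(weights)) {
    stop("weighted_mean aggregation requires country weights", call. = FALSE)
  }

  cells <- dplyr::distinct(
    tibble::as_tibble(projection),
    .data$region, .data$stratum_level, .data$year
  )
  res <- vector("list", nrow(cells))
  reg_draws <- matrix(NA_real_, nrow(draws), nrow(cells))
  for (i in seq_len(nrow(cells))) {
    idx <- which(projection$region == cells$region[i] &
      projection$stratum_level == cells$stratum_level[i] &
      projection$year == cells$year[i])
    cs <- projection$unit[idx]
    yi <- logit(draws[, idx, drop = FALSE] / 100, eps = 1e-9)
    if (method == "re_meta") {
      vi <- apply(yi, 2, stats::var)
      vi <- pmax(vi, 1e-12)
      pool <- dl_pool_draws(yi, vi)
      pooled <- pool$pooled
      het <- mean(sqrt(pool$tau2))
      used_w <- rep(NA_real_, length(cs))
    } else {
      w <- weights[cs]
      if (any(is.na(w))) {
        stop(sprintf(
          "missing weights for: %s",
          paste(cs[is.na(w)], collapse = ", ")
        ), call. = FALSE)
      }
      used_w <- w / sum(w)
      pooled <- as.numeric(yi %*% used_w)
      het <- 0
    }
    cci <- 100 * inv_logit(pooled)
    reg_draws[, i] <- cci
    q <- stats::quantile(cci, c(0.025, 0.975), names = FALSE)
    p <- mean(cci >= target)
    res[[i]] <- tibble::tibble(
      unit = cells$region[i], unit_type = "region",
      stratum_level = cells$stratum_level[i], year = cells$year[i],
      mean = mean(cci), cri_low = q[1], cri_high = q[2],
      p_target = p, on_track = p >= threshold,
      het_sd = het, n_countries = length(cs), method = method,
      weights = list(stats::setNames(used_w, cs))
    )
  }
  out <- dplyr::bind_rows(res)
  structure(out,
    class = c("cci_regional", class(out)),
    draws = reg_draws, target = target, threshold = threshold
  )
}

#' Count units on track to reach the coverage target
#'
#' @param projection A `cci_projection` or `cci_regional` table (or any
#'   tibble with `unit`, `year`, `stratum_level`, `p_target`).
#' @param year Evaluation year (default 2030).
#' @param stratum_level Stratum to evaluate (default `"national"` when
#'   present, otherwise all rows at `year`).
#' @param threshold Probability threshold (default 0.70).
#' @return List: `count`, `units` (character vector of on-track units),
#'   `year`, `threshold`.
#' @export
count_on_track <- function(projection, year = 2030, stratum_level = NULL,
                           threshold = 0.70) {
  rows <- dplyr::filter(tibble::as_tibble(projection), .data$year == !!year)
  if (is.null(stratum_level) && "national" %in% rows$stratum_level) {
    stratum_level <- "national"
  }
  if (!is.null(stratum_level)) {
    rows <- dplyr::filter(rows, .data$stratum_level %in% !!stratum_level)
  }
  if (nrow(rows) == 0) stop("no projection rows at the requested year/stratum", call. = FALSE)
  on <- rows$unit[rows$p_target >= threshold]
  list(
    count = length(unique(on)), units = unique(on),
    year = year, threshold = threshold
  )
}
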