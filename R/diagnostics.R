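#' Gelman-Rubin potential scale reduction factor (PSRF)
#'
#' Classic (non-split) Gelman-Rubin statistic
#' \deqn{\hat R = \sqrt{\frac{(n-1)/n\, W + B/n}{W}}}
#' where `W` is the mean within-chain variance and `B/n` the variance of the
#' chain means. Values near 1 indicate convergence; parameters above the
#' threshold (1.1 by default elsewhere in the package) are flagged. A
#' `split` option halves each chain first, which also detects within-chain
#' trends.
#'
#' @param chains Matrix (iterations x chains) or list of equal-length
#'   numeric vectors, one per chain.
#' @param split Split each chain in half before computing (default `FALSE`).
#' @return The PSRF value; `NaN` with a warning when every chain has zero
#'   within-chain variance.
#' @export
#' @examples
#' set.seed(1)
#' psrf(matrix(rnorm(2000), ncol = 2))
psrf <- function(chains, split = FALSE) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2) stop("PSRF needs at least 2 chains", call. = FALSE)
  if (nrow(chains) < 10) stop("chains too short (need >= 10 draws)", call. = FALSE)
  if (split) {
    half <- nrow(chains) %/% 2
    chains <- cbind(
      chains[seq_len(half), , drop = FALSE],
      chains[half + seq_len(half), , drop = FALSE]
    )
  }
  n <- nrow(chains)
  W <- mean(apply(chains, 2, stats::var))
  B_over_n <- stats::var(colMeans(chains))
  if (W == 0) {
    warning("zero within-chain variance in all chains; PSRF undefined", call. = FALSE)
    return(NaN)
  }
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

#' Per-parameter PSRF table for a fitted model
#'
#' @param fit A `cci_fit`.
#' @param parameters Optional subset of parameter names (default: all).
#' @param split Passed to [psrf()].
#' @return Tibble with columns `parameter`, `psrf`.
#' @export
fit_psrf <- function(fit, parameters = NULL, split = FALSE) {
  stopifnot(inherits(fit, "cci_fit"))
  parameters <- parameters %||% fit$param_names
  tibble::tibble(
    parameter = parameters,
    psrf = vapply(
      parameters,
      function(nm) psrf(sapply(fit$draws, function(m) m[, nm]), split = split),
      numeric(1)
    )
  )
}

#' Iterative variance-inflation-factor screen for candidate covariates
#'
#' For each candidate, VIF_j = 1 / (1 - R^2_j) from the least-squares
#' regression of that covariate on all other candidates. While any VIF
#' exceeds the threshold, the single worst covariate is removed (ties broken
#' alphabetically) and all VIFs recomputed; every round is reported.
#' Perfectly collinear covariates get `Inf` and are removed first. The
#' screen operates on the covariate columns only, never on stratum dummies
#' or intercepts.
#'
#' @param covariates Data frame containing the candidate columns (typically
#'   one row per country-year).
#' @param candidates Character vector (>= 2) of column names to screen.
#' @param threshold Elimination threshold (default 5).
#' @return A list of class `cci_vif`: `rounds` (tibble: `round`,
#'   `covariate`, `vif`, `removed`), `retained`, `eliminated`, `threshold`.
#' @export
vif_screen <- function(covariates, candidates, threshold = 5) {
  if (length(candidates) < 2) stop("need >= 2 candidate covariates", call. = FALSE)
  missing <- setdiff(candidates, names(covariates))
  if (length(missing) > 0) {
    stop(sprintf("candidates not in table: %s", paste(missing, collapse = ", ")),
      call. = FALSE
    )
  }
  dat <- as.data.frame(covariates[candidates])
  if (nrow(dat) < 3) stop("need >= 3 rows to compute VIFs", call. = FALSE)

  vif_one <- function(j, active) {
    others <- setdiff(active, j)
    fit <- stats::lm(
      stats::reformulate(others, response = j),
      data = dat
    )
    # summary.lm warns on exact fits; collinearity is a valid input here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }

  active <- sort(candidates)
  rounds <- list()
  eliminated <- character(0)
  round_i <- 0L
  repeat {
    round_i <- round_i + 1L
    vifs <- vapply(active, vif_one, numeric(1), active = active)
    # highest VIF first; alphabetical tie-break (active is sorted)
    drop <- if (any(vifs > threshold)) active[which.max(vifs)] else NA_character_
    rounds[[round_i]] <- tibble::tibble(
      round = round_i,
      covariate = active,
      vif = unname(vifs),
      removed = !is.na(drop) & active == drop
    )
    if (is.na(drop)) break
    eliminated <- c(eliminated, drop)
    active <- setdiff(active, drop)
    # VIF is undefined for a single remaining covariate; it is retained
    if (length(active) < 2) break
  }
  structure(
    list(
      rounds = dplyr::bind_rows(rounds),
      retained = active,
      eliminated = eliminated,
      threshold = threshold
    ),
    class = "cci_vif"
  )
}

#' @export
print.cci_vif <- function(x, ...) {
  cat(sprintf(
    "<cci_vif> threshold %g | retained: %s%s\n",
    x$threshold, paste(x$retained, collapse = ", "),
    if (length(x$eliminated)) {
      paste0(" | eliminated: ", paste(x$eliminated, collapse = ", "))
    } else {
      ""
    }
  ))
  invisible(x)
}

#' Per-draw deviance of a fitted model
#'
#' Returns the deviance (-2 log normal likelihood of logit-CCI) for every
#' posterior draw and at the plug-in posterior mean of all location
#' parameters with posterior-mean residual variance — the two inputs of the
#' Spiegelhalter DIC.
#'
#' @param fit A `cci_fit`.
#' @return List with `deviance` (vector, one per draw) and
#'   `deviance_at_mean` (scalar).
#' @export
deviance_draws <- function(fit) {
  stopifnot(inherits(fit, "cci_fit"))
  y <- fit$design$y
  mu <- fitted_draws(fit)
  m <- as_draws_matrix(fit)
  s2 <- m[, "sigma"]^2
  n <- length(y)
  sse <- rowSums(sweep(mu, 2, y)^2)
  dev <- n * log(2 * pi * s2) + sse / s2
  mu_bar <- colMeans(mu)
  s2_bar <- mean(s2)
  dev_mean <- n * log(2 * pi * s2_bar) + sum((y - mu_bar)^2) / s2_bar
  list(deviance = as.numeric(dev), deviance_at_mean = dev_mean)
}

#' Deviance information criterion
#'
#' `pD = mean(deviance) - deviance_at_mean` (effective number of
#' parameters) and `DIC = mean(deviance) + pD`.
#'
#' @param deviance Either a `cci_fit` (deviances computed via
#'   [deviance_draws()]) or a numeric vector of per-draw deviances.
#' @param deviance_at_mean Deviance at the posterior-mean parameters
#'   (required when `deviance` is a vector).
#' @return Tibble with columns `dic`, `p_d`, `mean_deviance`.
#' @export
compute_dic <- function(deviance, deviance_at_mean = NULL) {
  if (inherits(deviance, "cci_fit")) {
    dd <- deviance_draws(deviance)
    deviance <- dd$deviance
    deviance_at_mean <- dd$deviance_at_mean
  }
  if (length(deviance) < 100) stop("need >= 100 deviance draws", call. = FALSE)
  if (!all(is.finite(deviance)) || !is.finite(deviance_at_mean)) {
    stop("deviances must be finite", call. = FALSE)
  }
  dbar <- mean(deviance)
  p_d <- dbar - deviance_at_mean
  tibble::tibble(dic = dbar + p_d, p_d = p_d, mean_deviance = dbar)
}

#' Posterior predictive check
#'
#' For every posterior draw, a replicate data set is simulated from the
#' fitted likelihood at that draw's parameters; a discrepancy statistic of
#' the replicate CCI proportions (inverse-logit of the replicate response)
#' is compared with the same statistic of the observed proportions. The
#' Bayesian p-value is the fraction of draws whose replicate statistic
#' exceeds the observed one, counting ties as 1/2; values near 0.5 indicate
#' no evidence of misfit, values near 0 or 1 indicate systematic
#' discrepancy.
#'
#' @param fit A `cci_fit`.
#' @param statistic Discrepancy: `"mean"` (default), `"sd"`, or
#'   `"quantile"`.
#' @param prob Quantile level when `statistic = "quantile"`.
#' @param replicate_shift Logit-scale mean shift added to the replicate
#'   simulations (0 for an ordinary check; nonzero values exercise the
#'   check's power against systematic bias).
#' @param seed Integer seed for the replicate noise.
#' @return Tibble with columns `statistic`, `observed`, `p_value`.
#' @export
posterior_predictive_check <- function(fit, statistic = c("mean", "sd", "quantile"),
                                       prob = 0.5, replicate_shift = 0, seed = 1L) {
  stopifnot(inherits(fit, "cci_fit"))
  statistic <- match.arg(statistic)
  y <- fit$design$y
  mu <- fitted_draws(fit)
  sigma <- as_draws_matrix(fit)[, "sigma"]
  stat_fun <- switch(statistic,
    mean = mean,
    sd = stats::sd,
    quantile = function(x) stats::quantile(x, prob, names = FALSE)
  )
  obs <- stat_fun(inv_logit(y))
  withr::with_seed(seed, {
    noise <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu)) * sigma
    reps <- inv_logit(mu + replicate_shift + noise)
  })
  t_rep <- apply(reps, 1, stat_fun)
  tibble::tibble(
    statistic = statistic, observed = obs,
    p_value = ppc_pvalue(t_rep, obs)
  )
}

# Bayesian p-value with the half-tie convention: replicates exactly equal to
# the observed statistic count 1/2, so a degenerate "replicates == observed"
# comparison yields exactly 0.5 and swapping observed/replicate roles maps
# p to 1 - p.
ppc_pvalue <- function(t_rep, t_obs) {
  mean(t_rep > t_obs) + 0.5 * mean(t_rep == t_obs)
}

#' Prior-sensitivity comparison between two fits
#'
#' Compares posterior medians parameter by parameter between a baseline fit
#' (gamma hyperpriors) and a sensitivity fit (half-Cauchy hyperpriors):
#' reports the absolute difference of medians and that difference expressed
#' in units of the baseline posterior SD. A fixed effect whose shift exceeds
#' `threshold` posterior SDs is flagged.
#'
#' @param fit_a,fit_b Two `cci_fit` objects on the same design (same
#'   parameter set).
#' @param threshold Flag threshold in posterior-SD units (default 0.5).
#' @return Tibble: `parameter`, `median_a`, `median_b`, `abs_diff`,
#'   `posterior_sd`, `sd_ratio`, `fixed_effect`, `flag`.
#' @export
prior_sensitivity <- function(fit_a, fit_b, threshold = 0.5) {
  stopifnot(inherits(fit_a, "cci_fit"), inherits(fit_b, "cci_fit"))
  if (!identical(fit_a$param_names, fit_b$param_names)) {
    stop("fits have different parameter sets; refit on the same design", call. = FALSE)
  }
  ma <- as_draws_matrix(fit_a)
  mb <- as_draws_matrix(fit_b)
  med_a <- apply(ma, 2, stats::median)
  med_b <- apply(mb, 2, stats::median)
  sd_a <- apply(ma, 2, stats::sd)
  out <- tibble::tibble(
    parameter = fit_a$param_names,
    median_a = unname(med_a),
    median_b = unname(med_b),
    abs_diff = abs(unname(med_a - med_b)),
    posterior_sd = unname(sd_a),
    sd_ratio = abs(unname(med_a - med_b)) / unname(sd_a),
    fixed_effect = fit_a$param_names %in% fit_a$fixed_names
  )
  dplyr::mutate(out, flag = .data$fixed_effect & .data$sd_ratio > threshold)
}
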