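#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy posterior summaries of a fitted coverage model
#'
#' @param x A `cci_fit`.
#' @param parameters Which parameters to summarise: `"fixed"` (default),
#'   `"all"`, or a character vector of names.
#' @param conf.level Credible-interval level (default 0.95).
#' @param ... Unused.
#' @return Tibble: `term`, `estimate` (posterior mean), `std.error`
#'   (posterior SD), `conf.low`, `conf.high` (central interval), `psrf`.
#' @method tidy cci_fit
#' @export
tidy.cci_fit <- function(x, parameters = "fixed", conf.level = 0.95, ...) {
  nms <- if (identical(parameters, "fixed")) {
    x$fixed_names
  } else if (identical(parameters, "all")) {
    x$param_names
  } else {
    parameters
  }
  m <- as_draws_matrix(x)[, nms, drop = FALSE]
  a <- (1 - conf.level) / 2
  q <- apply(m, 2, stats::quantile, probs = c(a, 1 - a), names = FALSE)
  tibble::tibble(
    term = nms,
    estimate = unname(colMeans(m)),
    std.error = unname(apply(m, 2, stats::sd)),
    conf.low = q[1, ],
    conf.high = q[2, ],
    psrf = x$convergence$psrf[match(nms, x$convergence$parameter)]
  )
}

#' One-row model summary
#'
#' @param x A `cci_fit`.
#' @param ... Unused.
#' @return Tibble with `nobs`, `n_countries`, `n_regions`, `n_chains`,
#'   `n_draws`, `sigma` (posterior-mean residual SD), `dic`, `p_d`,
#'   `max_psrf`, `convergence_ok`.
#' @method glance cci_fit
#' @export
glance.cci_fit <- function(x, ...) {
  d <- compute_dic(x)
  tibble::tibble(
    nobs = length(x$design$y),
    n_countries = length(x$design$country_levels),
    n_regions = length(x$design$region_levels),
    n_chains = x$spec$chains,
    n_draws = x$n_draws,
    sigma = mean(as_draws_matrix(x)[, "sigma"]),
    dic = d$dic,
    p_d = d$p_d,
    max_psrf = max(
      x$convergence$psrf[x$convergence$parameter %in% x$fixed_names],
      na.rm = TRUE
    ),
    convergence_ok = x$convergence_ok
  )
}
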