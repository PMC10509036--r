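#' Ridit scores for ordered population groups
#'
#' The ridit (midpoint of the cumulative population-share interval) places
#' each ordered group on a 0-1 axis: `score_g = sum(shares below g) +
#' share_g / 2`. Five equal quintiles map to 0.1, 0.3, 0.5, 0.7, 0.9.
#'
#' @param shares Positive population shares summing to 1, in level order
#'   (lowest group first).
#' @return Numeric vector of strictly increasing scores in (0, 1).
#' @export
#' @examples
#' ridit_scores(rep(0.2, 5))
ridit_scores <- function(shares) {
  if (any(!is.finite(shares) | shares <= 0)) {
    stop("shares must be positive", call. = FALSE)
  }
  if (abs(sum(shares) - 1) > 1e-8) {
    stop("shares must sum to 1", call. = FALSE)
  }
  cumsum(shares) - shares / 2
}

#' Slope index of inequality (SII) across ordered strata
#'
#' Weighted least squares of per-stratum CCI on ridit scores, weights equal
#' to population shares. On the natural scale the SII is the fitted
#' difference between the extremes of the cumulative population ranking
#' (ridit 1 minus ridit 0), in percentage points. On the log scale the
#' regression uses the natural logarithm of the coverage proportion and the
#' fitted extremes are back-transformed before differencing, again reported
#' in percentage points.
#'
#' @param series Data frame with columns `level` (ordered, lowest first, in
#'   row order), `cci` (% scale), and optionally `share` (population
#'   shares; default equal).
#' @param scale `"natural"` (default) or `"log"`.
#' @return One-row tibble of class `cci_sii`: `sii` (percentage points),
#'   `scale`, `intercept`, `slope`, and a list-column `ridit` of per-level
#'   scores.
#' @export
#' @examples
#' sii(tibble::tibble(level = paste0("Q", 1:5), cci = c(40, 48, 55, 61, 70)))
sii <- function(series, scale = c("natural", "log")) {
  scale <- match.arg(scale)
  series <- tibble::as_tibble(series)
  if (nrow(series) < 2) stop("need >= 2 ordered levels", call. = FALSE)
  shares <- if ("share" %in% names(series)) {
    series$share
  } else {
    rep(1 / nrow(series), nrow(series))
  }
  r <- ridit_scores(shares / sum(shares))
  yy <- series$cci
  if (any(!is.finite(yy) | yy < 0 | yy > 100)) {
    stop("cci values must be in [0, 100] percent", call. = FALSE)
  }
  if (scale == "log") {
    if (any(yy <= 0)) stop("log scale requires strictly positive cci", call. = FALSE)
    yy <- log(yy / 100)
  }
  co <- wls_line(r, yy, shares)
  siival <- if (scale == "natural") {
    co[2]
  } else {
    100 * (exp(co[1] + co[2]) - exp(co[1]))
  }
  tibble::tibble(
    sii = unname(siival), scale = scale,
    intercept = unname(co[1]), slope = unname(co[2]),
    ridit = list(stats::setNames(r, series$level))
  ) |>
    structure(class = c("cci_sii", class(tibble::tibble())))
}

# Weighted least-squares line fit; closed-form normal equations.
wls_line <- function(x, y, w) {
  w <- w / sum(w)
  xb <- sum(w * x)
  yb <- sum(w * y)
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

# Vectorised natural-scale SII over posterior draws: cci_draws is
# draws x levels (% scale), shares a length-levels vector.
sii_draws <- function(cci_draws, shares) {
  shares <- shares / sum(shares)
  r <- ridit_scores(shares)
  xb <- sum(shares * r)
  xc <- r - xb
  # the weighted y-mean term cancels: slope = sum w (x - xb) y / sum w (x - xb)^2
  as.numeric(cci_draws %*% (shares * xc)) / sum(shares * xc^2)
}

#' Urban-rural absolute coverage gap
#'
#' The residence stratifier is nominal, so absolute inequality is the
#' signed percentage-point difference urban minus rural.
#'
#' @param urban,rural CCI values in % (vectorised).
#' @return Signed gap(s) in percentage points.
#' @export
#' @examples
#' urban_rural_gap(77.4, 47.1)
urban_rural_gap <- function(urban, rural) {
  stopifnot(all(urban >= 0 & urban <= 100), all(rural >= 0 & rural <= 100))
  urban - rural
}

#' Summarise the time trend of an inequality series
#'
#' @param data Data frame with columns `year` and `value` (an SII or gap
#'   series in percentage points), >= 2 time points.
#' @param tol Absolute-change tolerance below which the series is called
#'   stable (default 1e-8).
#' @return One-row tibble: `start_year`, `end_year`, `start`, `end`,
#'   `change` (end minus start), `direction` (`"narrowing"` when the
#'   magnitude of inequality shrinks, `"widening"` when it grows,
#'   `"stable"` otherwise).
#' @export
inequality_trend <- function(data, tol = 1e-8) {
  data <- dplyr::arrange(tibble::as_tibble(data), .data$year)
  if (nrow(data) < 2) stop("need >= 2 time points", call. = FALSE)
  s <- data$value[1]
  e <- data$value[nrow(data)]
  dmag <- abs(e) - abs(s)
  direction <- if (abs(dmag) <= tol) {
    "stable"
  } else if (dmag < 0) {
    "narrowing"
  } else {
    "widening"
  }
  tibble::tibble(
    start_year = data$year[1], end_year = data$year[nrow(data)],
    start = s, end = e, change = e - s, direction = direction
  )
}

#' Inequality table from projection draws
#'
#' Computes, per country and year, the inequality metric appropriate to the
#' fitted stratifier — the urban-rural gap for the residence variant, the
#' natural-scale SII for wealth or education — applying the operation to
#' every posterior draw so the credible interval is inherited from the
#' projection.
#'
#' @param projection A `cci_projection` with draws attached.
#' @param shares Optional population shares per stratum level (default
#'   equal shares, the construction of quintiles; a warning is issued for
#'   education, where true shares are country-specific).
#' @return Tibble: `unit`, `year`, `stratifier`, `metric`, `value` (% or
#'   percentage points), `cri_low`, `cri_high`.
#' @export
inequality_table <- function(projection, shares = NULL) {
  stopifnot(inherits(projection, "cci_projection"))
  draws <- attr(projection, "draws")
  levels <- unique(projection$stratum_level)
  if (all(c("urban", "rural") %in% levels)) {
    stratifier <- "residence"
  } else if (all(levels %in% c("Q1", "Q2", "Q3", "Q4", "Q5"))) {
    stratifier <- "wealth"
  } else {
    stratifier <- "education"
  }
  cells <- dplyr::distinct(tibble::as_tibble(projection), .data$unit, .data$year)
  out <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sel <- projection$unit == cells$unit[i] & projection$year == cells$year[i]
    if (stratifier == "residence") {
      iu <- which(sel & projection$stratum_level == "urban")
      ir <- which(sel & projection$stratum_level == "rural")
      if (length(iu) != 1 || length(ir) != 1) next
      vals <- draws[, iu] - draws[, ir]
      metric <- "urban_rural_gap"
    } else {
      ord <- stratum_levels_for(stratifier)
      ord <- ord[ord %in% levels]
      idx <- vapply(
        ord,
        function(l) which(sel & projection$stratum_level == l)[1],
        integer(1)
      )
      if (any(is.na(idx))) next
      sh <- shares %||% rep(1 / length(ord), length(ord))
      if (is.null(shares) && stratifier == "education") {
        warning(
          "education shares default to equal; supply country shares if known",
          call. = FALSE
        )
        shares <- sh # warn once
      }
      vals <- sii_draws(draws[, idx, drop = FALSE], sh)
      metric <- "sii"
    }
    q <- stats::quantile(vals, c(0.025, 0.975), names = FALSE)
    out[[i]] <- tibble::tibble(
      unit = cells$unit[i], year = cells$year[i],
      stratifier = stratifier, metric = metric,
      value = mean(vals), cri_low = q[1], cri_high = q[2]
    )
  }
  dplyr::bind_rows(out)
}
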