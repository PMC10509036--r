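# Build a projection object directly from a draws matrix, for contract tests
# that need exact control over the posterior.
make_projection <- function(draws, units, years = 2030, strata = "national",
                            regions = NULL, target = 80, threshold = 0.70) {
  grid <- tidyr::expand_grid(unit = units, stratum_level = strata, year = years)
  stopifnot(ncol(draws) == nrow(grid))
  qs <- apply(draws, 2, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
  out <- tibble::tibble(
    unit = grid$unit, unit_type = "country",
    region = (regions %||% stats::setNames(rep("R1", length(units)), units))[grid$unit],
    stratum_level = grid$stratum_level, year = grid$year,
    mean = colMeans(draws), cri_low = qs[1, ], cri_high = qs[2, ],
    p_target = colMeans(draws >= target)
  )
  out$on_track <- out$p_target >= threshold
  structure(out,
    class = c("cci_projection", class(out)),
    draws = draws, target = target, threshold = threshold
  )
}

test_that("prob_target handles the three canonical draw sets", {
  expect_equal(prob_target(rep(90, 500))$p_target, 1)
  expect_true(prob_target(rep(90, 500))$on_track)
  expect_equal(prob_target(rep(50, 500))$p_target, 0)
  expect_false(prob_target(rep(50, 500))$on_track)
  withr::with_seed(51, sym <- 80 + stats::rnorm(20000, 0, 5))
  expect_equal(prob_target(sym)$p_target, 0.5, tolerance = 0.02)
  # non-increasing in the target level
  withr::with_seed(52, d <- 70 + stats::rnorm(500, 0, 10))
  ps <- vapply(c(60, 70, 80, 90), function(t) prob_target(d, t)$p_target, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("widening posterior spread moves p_target in the expected direction", {
  withr::with_seed(53, base <- stats::rnorm(5000))
  below <- 70 + 5 * base # mean below the 80% target
  above <- 88 + 2 * base # mean above
  expect_gt(
    prob_target(70 + 15 * base)$p_target,
    prob_target(below)$p_target
  )
  expect_lt(
    prob_target(88 + 10 * base)$p_target,
    prob_target(above)$p_target
  )
})

test_that("DerSimonian-Laird pooling matches the hand-computed oracle", {
  yi <- c(0.20, 0.55, 0.95)
  vi <- c(0.04, 0.09, 0.16)
  # hand computation: w = 1/vi; Q = sum w (yi - ybar_f)^2;
  # c = sum(w) - sum(w^2)/sum(w); tau2 = (Q - 2)/c; w* = 1/(vi + tau2)
  w <- 1 / vi
  ybar_f <- sum(w * yi) / sum(w)
  Q <- sum(w * (yi - ybar_f)^2)
  cc <- sum(w) - sum(w^2) / sum(w)
  tau2 <- max(0, (Q - 2) / cc)
  wr <- 1 / (vi + tau2)
  est <- sum(wr * yi) / sum(wr)
  got <- dl_pool(yi, vi)
  expect_equal(got$estimate, est, tolerance = 1e-10)
  expect_equal(got$tau2, tau2, tolerance = 1e-10)
  expect_equal(got$q, Q, tolerance = 1e-10)
  expect_equal(got$se, sqrt(1 / sum(wr)), tolerance = 1e-10)
  expect_equal(got$weights[[1]], wr / sum(wr), tolerance = 1e-10)
})

test_that("dl_pool agrees with an independent meta-analysis implementation", {
  skip_if_not_installed("metafor")
  withr::with_seed(54, {
    yi <- stats::rnorm(6)
    vi <- stats::runif(6, 0.02, 0.3)
  })
  ref <- metafor::rma(yi = yi, vi = vi, method = "DL")
  got <- dl_pool(yi, vi)
  expect_equal(got$estimate, as.numeric(ref$beta), tolerance = 1e-8)
  expect_equal(got$tau2, ref$tau2, tolerance = 1e-8)
})

test_that("projection recovers the latent surface under low noise", {
  b <- simulate_bundle(
    scenario_config(
      n_regions = 2, countries_per_region = 3,
      surveys_min = 8, surveys_max = 12, single_survey_fraction = 0,
      noise_sd_logit = 0.03, seed = 61
    )
  )
  f <- quick_fit(b, chains = 2, iter = 1200, burn = 400, seed = 3)
  proj <- predict_cci(f, b$covariates, years = c(2000, 2010, 2020, 2030))
  expect_s3_class(proj, "cci_projection")
  expect_true(all(proj$cri_low <= proj$mean & proj$mean <= proj$cri_high))
  expect_true(all(proj$mean > 0 & proj$mean < 100))
  cmp <- dplyr::inner_join(
    tibble::as_tibble(proj),
    b$latent,
    by = c(unit = "country_id", year = "year", stratum_level = "stratum_level")
  )
  expect_equal(cmp$mean, 100 * cmp$cci_true, tolerance = 0.05)
  # most latent values inside the 95% band
  inside <- mean(100 * cmp$cci_true >= cmp$cri_low &
    100 * cmp$cci_true <= cmp$cri_high)
  expect_gt(inside, 0.8)
  expect_error(predict_cci(f, b$covariates, years = 2035), "missing")
  expect_error(predict_cci(f, b$covariates, strata = "Q1"), "not in the fitted")
})

test_that("degenerate draws give zero-width intervals and exact aggregates", {
  draws <- matrix(rep(c(60, 75, 90), each = 400), 400, 3)
  proj <- make_projection(draws, units = c("A", "B", "C"))
  expect_equal(proj$cri_low, proj$mean)
  expect_equal(proj$cri_high, proj$mean)
  reg <- aggregate_region(proj, method = "weighted_mean",
    weights = c(A = 1, B = 1, C = 2))
  # equal per-draw values: weighted logit-mean of constants
  expect_equal(reg$cri_low, reg$mean)
  manual <- 100 * inv_logit((logit(0.6, 1e-9) + logit(0.75, 1e-9) +
    2 * logit(0.9, 1e-9)) / 4)
  expect_equal(reg$mean, manual, tolerance = 1e-6)
})

test_that("single-country regions pass through and equal means collapse", {
  withr::with_seed(55, draws <- matrix(70 + stats::rnorm(500), 500, 1))
  proj <- make_projection(draws, units = "A")
  reg <- aggregate_region(proj, method = "re_meta")
  expect_equal(reg$mean, proj$mean, tolerance = 1e-10)
  expect_equal(reg$cri_low, proj$cri_low, tolerance = 1e-10)
  expect_equal(reg$het_sd, 0)

  # identical country draws: no heterogeneity, aggregate equals the common value
  withr::with_seed(56, common <- 65 + stats::rnorm(400, 0, 3))
  draws3 <- cbind(common, common, common)
  proj3 <- make_projection(draws3, units = c("A", "B", "C"))
  reg3 <- aggregate_region(proj3, method = "re_meta")
  expect_equal(reg3$mean, mean(common), tolerance = 1e-6)
  expect_equal(reg3$het_sd, 0, tolerance = 1e-8)
})

test_that("regional aggregates stay inside the constituent range per draw", {
  withr::with_seed(57, {
    draws <- cbind(
      50 + stats::rnorm(300, 0, 4),
      65 + stats::rnorm(300, 0, 6),
      80 + stats::rnorm(300, 0, 3)
    )
  })
  proj <- make_projection(draws, units = c("A", "B", "C"))
  for (m in c("re_meta", "weighted_mean")) {
    reg <- aggregate_region(proj, method = m, weights = c(A = 3, B = 1, C = 1))
    rd <- attr(reg, "draws")
    expect_true(all(rd >= apply(draws, 1, min) - 1e-9))
    expect_true(all(rd <= apply(draws, 1, max) + 1e-9))
  }
  expect_error(aggregate_region(proj, method = "weighted_mean"), "weights")
  expect_error(
    aggregate_region(proj, method = "weighted_mean", weights = c(A = 1, B = 1)),
    "missing weights"
  )
})

test_that("count_on_track counts and lists units at the threshold", {
  withr::with_seed(58, {
    draws <- cbind(
      85 + stats::rnorm(400, 0, 1), # clearly above target
      83 + stats::rnorm(400, 0, 1),
      60 + stats::rnorm(400, 0, 1),
      79 + stats::rnorm(400, 0, 0.2) # just below
    )
  })
  proj <- make_projection(draws, units = c("A", "B", "C", "D"))
  got <- count_on_track(proj)
  expect_identical(got$count, 2L)
  expect_setequal(got$units, c("A", "B"))
  expect_identical(count_on_track(proj, threshold = 0)$count, 4L)
  all_on <- make_projection(matrix(95, 400, 4), units = c("A", "B", "C", "D"))
  expect_identical(count_on_track(all_on)$count, 4L)
  expect_error(count_on_track(proj, year = 1999), "no projection rows")
})
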