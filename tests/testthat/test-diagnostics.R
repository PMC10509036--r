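test_that("psrf matches its closed form on constructed chains", {
  withr::with_seed(31, x <- stats::rnorm(1000))
  # identical chains: B = 0, PSRF = sqrt((n-1)/n)
  expect_equal(psrf(cbind(x, x)), sqrt(999 / 1000), tolerance = 1e-10)
  # well-separated chains are dominated by between-chain variance
  withr::with_seed(32, {
    far <- cbind(stats::rnorm(500, -10), stats::rnorm(500, 10))
  })
  expect_gt(psrf(far), 5)
  # direct recomputation on random chains
  withr::with_seed(33, ch <- matrix(stats::rnorm(900), ncol = 3))
  n <- nrow(ch)
  W <- mean(apply(ch, 2, var))
  B_n <- var(colMeans(ch))
  expect_equal(psrf(ch), sqrt(((n - 1) / n * W + B_n) / W), tolerance = 1e-12)
})

test_that("psrf is affine-invariant and consistent for iid chains", {
  withr::with_seed(34, ch <- matrix(stats::rnorm(4000), ncol = 4))
  expect_equal(psrf(3.7 * ch - 2), psrf(ch), tolerance = 1e-10)
  expect_lt(abs(psrf(ch) - 1), 0.02)
  expect_warning(p <- psrf(matrix(1, 100, 2)), "zero within-chain")
  expect_true(is.nan(p))
  expect_error(psrf(matrix(0, 100, 1)), "2 chains")
  expect_error(psrf(matrix(0, 5, 2)), "short")
})

test_that("split-chain psrf detects within-chain trends the classic form misses", {
  trend <- seq(-2, 2, length.out = 1000)
  classic <- psrf(cbind(trend, trend))
  expect_lt(classic, 1) # B = 0 exactly
  expect_gt(psrf(cbind(trend, trend), split = TRUE), 1.5)
})

test_that("VIF screen matches brute-force auxiliary regressions", {
  # orthogonal, mean-zero design: all VIFs exactly 1
  x1 <- rep(c(1, -1), 30)
  x2 <- rep(c(1, 1, -1, -1), 15)
  x3 <- rep(c(1, -1, -1, 1), 15)
  vr <- vif_screen(tibble::tibble(a = x1, b = x2, c = x3), c("a", "b", "c"))
  expect_equal(vr$rounds$vif, rep(1, 3), tolerance = 1e-10)
  expect_identical(vr$retained, c("a", "b", "c"))

  # correlated covariates: VIF_j = 1/(1 - R2_j) via normal equations
  withr::with_seed(41, {
    z <- stats::rnorm(60)
    dat <- tibble::tibble(
      p = z + stats::rnorm(60, 0, 0.6),
      q = z + stats::rnorm(60, 0, 0.8),
      r = stats::rnorm(60)
    )
  })
  vr2 <- vif_screen(dat, c("p", "q", "r"), threshold = 1e6)
  oracle_vif <- function(j, others) {
    M <- cbind(1, as.matrix(dat[others]))
    y <- dat[[j]]
    beta <- solve(crossprod(M), crossprod(M, y))
    res <- y - M %*% beta
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    1 / (1 - r2)
  }
  got <- vr2$rounds[vr2$rounds$round == 1, ]
  for (j in c("p", "q", "r")) {
    expect_equal(got$vif[got$covariate == j],
      oracle_vif(j, setdiff(c("p", "q", "r"), j)),
      tolerance = 1e-10
    )
  }
})

test_that("perfect collinearity yields infinite VIF and first-round removal", {
  withr::with_seed(42, {
    dat <- tibble::tibble(u = stats::rnorm(30), v = stats::rnorm(30))
  })
  dat$u_copy <- dat$u
  vr <- vif_screen(dat, c("u", "u_copy", "v"))
  r1 <- vr$rounds[vr$rounds$round == 1, ]
  expect_true(all(is.infinite(r1$vif[r1$covariate %in% c("u", "u_copy")])))
  # alphabetical tie-break removes "u" first
  expect_identical(r1$covariate[r1$removed], "u")
  expect_identical(vr$retained, c("u_copy", "v"))
  expect_error(vif_screen(dat, "u"), ">= 2")
})

test_that("DIC follows its defining algebra", {
  expect_error(compute_dic(rep(1, 50), 1), ">= 100")
  expect_error(compute_dic(c(rep(1, 200), NA), 1), "finite")
  # constant deviance: pD = 0, DIC = the deviance
  d <- compute_dic(rep(12.5, 200), 12.5)
  expect_equal(d$p_d, 0)
  expect_equal(d$dic, 12.5)
  # random inputs: formula identity
  withr::with_seed(43, dev <- stats::rgamma(500, 5, 1))
  d2 <- compute_dic(dev, 3.3)
  expect_equal(d2$p_d, mean(dev) - 3.3)
  expect_equal(d2$dic, mean(dev) + d2$p_d)
})

test_that("pD approximates the effective parameter count in a conjugate fit", {
  b <- simulate_bundle(
    scenario_config(
      n_regions = 1, countries_per_region = 1,
      surveys_min = 10, surveys_max = 10, single_survey_fraction = 0,
      noise_sd_logit = 0.1, seed = 8
    ),
    stratum_type = "national"
  )
  f <- suppressWarnings(fit_cci_model(
    b$panel, b$covariates,
    variant = "national", covariate_names = character(0),
    chains = 2, iter = 3000, burn = 500, fix_sigma = 0.1, seed = 4
  ))
  d <- compute_dic(f)
  # intercept + year slope with known tau: about two effective parameters
  expect_equal(d$p_d, 2, tolerance = 0.3)
  # and pD is non-negative on a hierarchical example
  sh <- shared_fit()
  expect_gt(compute_dic(sh$fit)$p_d, 0)
})

test_that("the ppc tie convention and equivariance hold", {
  ppc_pvalue <- ccitrend:::ppc_pvalue
  expect_identical(ppc_pvalue(rep(0.4, 100), 0.4), 0.5)
  withr::with_seed(44, t_rep <- stats::rnorm(200))
  expect_equal(ppc_pvalue(t_rep, 0.3), 1 - ppc_pvalue(-t_rep, -0.3))
})

test_that("posterior predictive checks flag shifted replicates but not good fits", {
  sh <- shared_fit()
  p0 <- posterior_predictive_check(sh$fit, seed = 2)
  expect_gt(p0$p_value, 0.05)
  expect_lt(p0$p_value, 0.95)
  expect_gt(posterior_predictive_check(sh$fit, replicate_shift = 2, seed = 2)$p_value, 0.95)
  expect_lt(posterior_predictive_check(sh$fit, replicate_shift = -2, seed = 2)$p_value, 0.05)
  psd <- posterior_predictive_check(sh$fit, statistic = "sd", seed = 2)
  expect_true(psd$p_value >= 0 && psd$p_value <= 1)
})

test_that("prior sensitivity reports zero for identical fits and validates inputs", {
  sh <- shared_fit()
  s <- prior_sensitivity(sh$fit, sh$fit)
  expect_true(all(s$abs_diff == 0))
  expect_false(any(s$flag))
  b_small <- simulate_bundle(scenario_config(
    n_regions = 2, countries_per_region = 2,
    surveys_min = 2, surveys_max = 3, seed = 23
  ))
  f_small <- quick_fit(b_small, iter = 400, burn = 200)
  expect_error(prior_sensitivity(sh$fit, f_small), "different parameter")
})
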