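test_that("ridit scores are cumulative-midpoint positions", {
  expect_equal(ridit_scores(rep(0.2, 5)), c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(ridit_scores(c(0.5, 0.5)), c(0.25, 0.75))
  expect_equal(ridit_scores(c(0.2, 0.8)), c(0.1, 0.6))
  withr::with_seed(71, {
    sh <- stats::runif(6)
    sh <- sh / sum(sh)
  })
  r <- ridit_scores(sh)
  expect_true(all(diff(r) > 0))
  expect_true(all(r > 0 & r < 1))
  expect_error(ridit_scores(c(0.5, 0, 0.5)), "positive")
  expect_error(ridit_scores(c(0.4, 0.4)), "sum to 1")
})

test_that("SII reproduces exact linear series and closed forms", {
  q5 <- paste0("Q", 1:5)
  # constant series: zero inequality on both scales
  const <- tibble::tibble(level = q5, cci = rep(55, 5))
  expect_equal(sii(const)$sii, 0)
  expect_equal(sii(const, scale = "log")$sii, 0, tolerance = 1e-10)
  # exactly linear in ridit: SII equals the slope
  lin <- tibble::tibble(level = q5, cci = 40 + 20 * c(0.1, 0.3, 0.5, 0.7, 0.9))
  expect_equal(sii(lin)$sii, 20, tolerance = 1e-10)
  # two-level closed form: slope = (hi - lo) / (ridit_hi - ridit_lo)
  two <- tibble::tibble(level = c("low", "high"), cci = c(42, 66))
  expect_equal(sii(two)$sii, (66 - 42) / (0.75 - 0.25), tolerance = 1e-10)
})

test_that("SII equals the brute-force weighted normal equations", {
  withr::with_seed(72, {
    for (i in 1:10) {
      shares <- stats::runif(5, 0.5, 2)
      shares <- shares / sum(shares)
      cci <- stats::runif(5, 20, 90)
      series <- tibble::tibble(level = paste0("Q", 1:5), share = shares, cci = cci)
      r <- ridit_scores(shares)
      M <- cbind(1, r)
      Wm <- diag(shares)
      coef <- solve(t(M) %*% Wm %*% M, t(M) %*% Wm %*% cci)
      got <- sii(series)
      expect_equal(got$sii, coef[2], tolerance = 1e-10)
      expect_equal(got$intercept, coef[1], tolerance = 1e-10)
      # log scale against the same normal equations on log proportions
      coefl <- solve(t(M) %*% Wm %*% M, t(M) %*% Wm %*% log(cci / 100))
      gotl <- sii(series, scale = "log")
      expect_equal(gotl$sii,
        100 * (exp(sum(coefl)) - exp(coefl[1])),
        tolerance = 1e-10
      )
    }
  })
})

test_that("SII shifts and reflections behave as an absolute inequality measure", {
  withr::with_seed(73, cci <- stats::runif(5, 30, 70))
  series <- tibble::tibble(level = paste0("Q", 1:5), cci = cci)
  shifted <- dplyr::mutate(series, cci = cci + 15)
  expect_equal(sii(series)$sii, sii(shifted)$sii, tolerance = 1e-10)
  reversed <- series[5:1, ]
  expect_equal(sii(reversed)$sii, -sii(series)$sii, tolerance = 1e-10)
  expect_error(sii(series[1, ]), ">= 2")
  expect_error(
    sii(tibble::tibble(level = c("a", "b"), cci = c(0, 50)), scale = "log"),
    "positive"
  )
})

test_that("urban-rural gap is the signed percentage-point difference", {
  expect_equal(urban_rural_gap(80, 80), 0)
  expect_equal(urban_rural_gap(77.4, 47.1), 30.3)
  withr::with_seed(74, {
    u <- stats::runif(20, 0, 100)
    r <- stats::runif(20, 0, 100)
  })
  expect_equal(urban_rural_gap(u, r), -urban_rural_gap(r, u))
  expect_error(urban_rural_gap(105, 50), "urban")
})

test_that("inequality trends classify narrowing, widening and stable series", {
  const <- tibble::tibble(year = c(2000, 2030), value = c(12, 12))
  got <- inequality_trend(const)
  expect_equal(got$change, 0)
  expect_identical(got$direction, "stable")
  narrowing <- tibble::tibble(year = seq(2000, 2030, 5),
    value = seq(30, 18, length.out = 7))
  got2 <- inequality_trend(narrowing)
  expect_equal(got2$change, -12)
  expect_identical(got2$direction, "narrowing")
  expect_lte(got2$change, -10) # at least a 10-point projected reduction
  # oracle recomputation on random series, including sign-crossing ones
  withr::with_seed(75, {
    for (i in 1:20) {
      v <- stats::rnorm(5, 0, 15)
      series <- tibble::tibble(year = 2000 + 0:4 * 5, value = v)
      got <- inequality_trend(series)
      expect_equal(got$change, v[5] - v[1])
      dmag <- abs(v[5]) - abs(v[1])
      expect_identical(
        got$direction,
        if (abs(dmag) <= 1e-8) "stable" else if (dmag < 0) "narrowing" else "widening"
      )
    }
  })
  expect_error(inequality_trend(const[1, ]), ">= 2")
})

test_that("per-draw and point-estimate inequality agree for degenerate draws", {
  units <- c("A", "B")
  q5 <- paste0("Q", 1:5)
  grid <- tidyr::expand_grid(unit = units, stratum_level = q5, year = 2030)
  point <- c(40, 48, 55, 61, 70, 35, 50, 60, 70, 85)
  draws <- matrix(rep(point, each = 300), 300, length(point))
  proj <- structure(
    tibble::tibble(
      unit = grid$unit, unit_type = "country", region = "R1",
      stratum_level = grid$stratum_level, year = grid$year,
      mean = point, cri_low = point, cri_high = point,
      p_target = as.numeric(point >= 80), on_track = point >= 80
    ),
    class = c("cci_projection", "tbl_df", "tbl", "data.frame"),
    draws = draws, target = 80, threshold = 0.7
  )
  tab <- inequality_table(proj)
  expect_identical(nrow(tab), 2L)
  expect_identical(unique(tab$metric), "sii")
  for (i in seq_along(units)) {
    direct <- sii(tibble::tibble(
      level = q5, cci = point[grid$unit == units[i]]
    ))$sii
    expect_equal(tab$value[tab$unit == units[i]], direct, tolerance = 1e-10)
    expect_equal(tab$cri_low[tab$unit == units[i]], direct, tolerance = 1e-10)
  }
})

test_that("inequality_table computes urban-rural gaps from residence projections", {
  units <- c("A", "B")
  levs <- c("national", "urban", "rural")
  grid <- tidyr::expand_grid(unit = units, stratum_level = levs, year = c(2020, 2030))
  withr::with_seed(76, draws <- matrix(stats::runif(200 * nrow(grid), 30, 90),
    200, nrow(grid)))
  proj <- structure(
    tibble::tibble(
      unit = grid$unit, unit_type = "country", region = "R1",
      stratum_level = grid$stratum_level, year = grid$year,
      mean = colMeans(draws), cri_low = 0, cri_high = 100,
      p_target = 0, on_track = FALSE
    ),
    class = c("cci_projection", "tbl_df", "tbl", "data.frame"),
    draws = draws, target = 80, threshold = 0.7
  )
  tab <- inequality_table(proj)
  expect_identical(unique(tab$metric), "urban_rural_gap")
  iu <- which(grid$unit == "A" & grid$stratum_level == "urban" & grid$year == 2030)
  ir <- which(grid$unit == "A" & grid$stratum_level == "rural" & grid$year == 2030)
  expect_equal(
    tab$value[tab$unit == "A" & tab$year == 2030],
    mean(draws[, iu] - draws[, ir])
  )
})
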