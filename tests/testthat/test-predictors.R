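test_that("CUI reproduces the hand-worked Ekman example", {
  # 10 m/s alongshore equatorward wind, meridional west-facing coast, 43N
  cui <- compute_cui(0, -10, coast_angle = 90, lat = 43)
  tau <- 1.22 * 1.4e-3 * 10 * 10
  expect_equal(tau, 0.1708)
  f <- 2 * 7.2921e-5 * sin(43 * pi / 180)
  expect_equal(f, 9.946e-5, tolerance = 1e-4)
  expect_equal(cui, tau / (1025 * f) * 100, tolerance = 1e-12)
  expect_equal(cui, 167.5, tolerance = 1e-3)
})

test_that("CUI symmetries and edge cases", {
  expect_equal(compute_cui(0, 0, 90, 43), 0)
  w <- c(3.2, -7.5)
  expect_equal(compute_cui(w[1], w[2], 72, 40, cui_params()),
               -compute_cui(-w[1], -w[2], 72, 40, cui_params()))
  # poleward alongshore wind is downwelling-favourable (negative)
  expect_lt(compute_cui(0, 10, 90, 43), 0)
  # cross-shore wind drives purely alongshore Ekman transport: CUI = 0
  expect_equal(compute_cui(-10, 0, 90, 43), 0, tolerance = 1e-12)
  expect_error(compute_cui(1, 1, 90, 0.5), "equator")
})

test_that("favourable-day rule is strictly greater-than", {
  expect_false(favourable_upwelling_day(16.0))
  expect_true(favourable_upwelling_day(16.01))
  expect_false(favourable_upwelling_day(-5))
  expect_identical(favourable_upwelling_day(c(10, 20), threshold = 15),
                   c(FALSE, TRUE))
})

test_that("longest_run_above enumerates maximal runs", {
  expect_identical(longest_run_above(numeric(0), 18), 0L)
  expect_identical(longest_run_above(c(17, 19, 19, 18.5, 17, 19), 18), 3L)
  expect_identical(longest_run_above(rep(10, 50), 18), 0L)
  expect_identical(longest_run_above(rep(20, 7), 18), 7L)
  # bounded by series length (property over random series)
  set.seed(1)
  for (k in 1:20) {
    x <- rnorm(sample(1:60, 1), mean = 18, sd = 2)
    r <- longest_run_above(x, 18)
    expect_gte(r, 0L)
    expect_lte(r, length(x))
  }
})

test_that("winter predictors draw Oct-Dec from the previous calendar year", {
  seasons <- default_seasons()
  # two years of synthetic days with a marker value in Oct-Dec of year 1
  year <- rep(2000:2001, each = 365)
  month <- rep(kelpcast:::.MONTH_OF_DOY, 2)
  values <- numeric(730)
  values[year == 2000 & month %in% 10:12] <- 50   # should enter winter 2001
  values[year == 2001 & month %in% 10:12] <- -50  # should not
  expect_equal(
    seasonal_stat(values, year, month, seasons$winter, 2001, stat_max()), 50)
  # constant series, stat = max
  expect_equal(
    seasonal_stat(rep(3.3, 730), year, month, seasons$spring, 2001,
                  stat_max()), 3.3)
  # season entirely below threshold
  expect_identical(
    seasonal_stat(rep(10, 730), year, month, seasons$winter, 2001,
                  stat_longest_run_above(18)), 0L)
  # winter of the first year is incomplete (no previous October)
  expect_error(
    seasonal_stat(values, year, month, seasons$winter, 2000, stat_max()),
    "incomplete season")
  # previous summer of year t comes entirely from year t-1
  values2 <- numeric(730)
  values2[year == 2000 & month %in% 7:9] <- 9
  expect_equal(
    seasonal_stat(values2, year, month, seasons$prev_summer, 2001,
                  stat_max()), 9)
})

test_that("season definitions validate their month sets", {
  expect_error(season_definition("x", integer(0)))
  expect_error(season_definition("x", c(1, 1, 2)))
  expect_error(season_definition("x", c(0, 3)))
  expect_error(season_definition("x", 1:3, prev_year_months = 5))
})

test_that("predictor stack is a pure function with the configured columns", {
  g <- tiny_grid(4)
  env <- generate_daily_environment(g, 2000:2002, climate_params(seed = 2))
  s1 <- build_predictor_stack(env)
  s2 <- build_predictor_stack(env)
  expect_identical(s1, s2)
  expect_setequal(predictor_names(s1),
                  c("sst_winter_run18", "sst_spring_run18", "sst_winter_max",
                    "cui_spring_runfav", "swh_winter_max", "swh_spring_run3"))
  expect_equal(sort(unique(s1$year)), 2001:2002)  # first winter incomplete
  expect_equal(nrow(s1), 4 * 2)
  expect_false(anyNA(s1))
  # consecutive-day counts bounded by season length
  expect_true(all(s1$sst_winter_run18 >= 0 & s1$sst_winter_run18 <= 151))
  expect_true(all(s1$sst_spring_run18 >= 0 & s1$sst_spring_run18 <= 122))
})

test_that("a 20-day heat wave shows up as a 20-day winter run", {
  g <- tiny_grid(12)
  # quiet world, cool enough that only the episode exceeds 18 degC
  # episode in November of 2000 -> winter predictor of 2001
  hw <- list(year = 2000, start_doy = 310L, duration_days = 20L,
             amplitude = 6, cells = c(4L, 8L))
  p1 <- quiet_params(sst_mean = 13, seasonal_amp = 1,
                     heatwaves = list(hw))
  env <- generate_daily_environment(g, 2000:2001, p1)
  s <- build_predictor_stack(env)
  hit <- s[s$year == 2001 & s$cell_id == 6, ]
  miss <- s[s$year == 2001 & s$cell_id == 1, ]
  expect_equal(hit$sst_winter_run18, 20)
  expect_equal(miss$sst_winter_run18, 0)
})
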