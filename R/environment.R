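#' Climate scenario parameters for the synthetic coastal world
#'
#' Bundles everything [generate_daily_environment()] needs: the latitudinal
#' mean and seasonal cycle of sea-surface temperature (SST), a multi-year
#' warming trend, AR(1) anomaly structure, discrete heat-wave episodes, the
#' seasonal wave climate, and wind regimes that produce spatially localized
#' upwelling zones.
#'
#' Defaults describe a plausible warm-temperate eastern-boundary coast:
#' ~17 degC mean SST at 40 deg latitude falling 0.6 degC per degree poleward,
#' a 3.5 degC seasonal half-amplitude peaking in late August (day 233), a
#' 0.25 degC/decade warming trend, and spring (March-June) upwelling winds.
#'
#' @param sst_mean mean annual SST (degC) at `lat_ref`.
#' @param lat_ref reference latitude (deg) for `sst_mean`.
#' @param lat_gradient SST decrease per degree of latitude northward (degC).
#' @param seasonal_amp half-amplitude of the seasonal SST cycle (degC).
#' @param peak_doy day-of-year of the SST maximum.
#' @param trend_c_per_decade linear warming trend (degC/decade), applied as a
#'   constant offset per calendar year.
#' @param ar_phi,ar_sd autocorrelation and innovation sd (degC) of the
#'   coast-wide daily SST anomaly (AR(1); `ar_sd = 0` disables it).
#' @param cell_ar_sd innovation sd (degC) of independent per-cell AR(1)
#'   anomalies (same `ar_phi`).
#' @param heatwaves list of episodes, each a list with `year`, `start_doy`,
#'   `duration_days`, `amplitude` (degC, additive) and `cells = c(from, to)`
#'   (inclusive 0-based cell_id range).
#' @param upwelling_zones list of zones, each a list with
#'   `cells = c(from, to)`, `months` (e.g. `3:6`) and `speed` (m/s) of the
#'   alongshore equatorward wind blown during those months.
#' @param upwelling_sst_cooling degC subtracted from SST inside upwelling
#'   zones during their months (upwelled water is cold); default 0.
#' @param wind_sd sd (m/s) of isotropic background wind noise.
#' @param swh_base,swh_amp,swh_peak_doy mean, seasonal half-amplitude (m) and
#'   peak day of significant wave height (winter-peaked by default).
#' @param swh_sd innovation sd (m) of the AR(1) wave anomaly.
#' @param seed integer seed for all stochastic components.
#' @return a `climate_params` list.
#' @export
climate_params <- function(sst_mean = 17, lat_ref = 40, lat_gradient = 0.6,
                           seasonal_amp = 3.5, peak_doy = 233,
                           trend_c_per_decade = 0.25,
                           ar_phi = 0.8, ar_sd = 0.4, cell_ar_sd = 0.15,
                           heatwaves = list(),
                           upwelling_zones = list(),
                           upwelling_sst_cooling = 0,
                           wind_sd = 2,
                           swh_base = 1.5, swh_amp = 1.0, swh_peak_doy = 15,
                           swh_sd = 0.4,
                           seed = 1) {
  stopifnot(seasonal_amp >= 0, ar_sd >= 0, cell_ar_sd >= 0, wind_sd >= 0,
            swh_amp >= 0, swh_sd >= 0)
  for (hw in heatwaves) {
    stopifnot(is.numeric(hw$amplitude), length(hw$cells) == 2)
  }
  structure(list(
    sst_mean = sst_mean, lat_ref = lat_ref, lat_gradient = lat_gradient,
    seasonal_amp = seasonal_amp, peak_doy = peak_doy,
    trend_c_per_decade = trend_c_per_decade,
    ar_phi = ar_phi, ar_sd = ar_sd, cell_ar_sd = cell_ar_sd,
    heatwaves = heatwaves, upwelling_zones = upwelling_zones,
    upwelling_sst_cooling = upwelling_sst_cooling,
    wind_sd = wind_sd,
    swh_base = swh_base, swh_amp = swh_amp, swh_peak_doy = swh_peak_doy,
    swh_sd = swh_sd, seed = seed
  ), class = "climate_params")
}

.ar1_series <- function(n, phi, sd) {
  if (sd <= 0) return(numeric(n))
  innov <- rnorm(n, 0, sd)
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Generate daily environment series on a synthetic coastline
#'
#' Per-cell daily SST, significant wave height and surface wind over a span
#' of 365-day years. SST is built additively: latitudinal mean + seasonal
#' sinusoid + per-year linear trend + AR(1) anomalies (coast-wide and
#' per-cell) + heat-wave pulses, so each component is exactly recoverable by
#' differencing runs that toggle it. Wind is isotropic noise everywhere
#' except inside configured upwelling zones during their season, where a
#' deterministic alongshore equatorward component (upwelling-favourable on
#' this west-facing coast) is added.
#'
#' @param grid a `coastline_grid`.
#' @param years integer vector of consecutive calendar years.
#' @param params a [climate_params()] object.
#' @return a `daily_env` list with matrices `sst`, `swh`, `wind_u`, `wind_v`
#'   (cells x days) and day-index vectors `year`, `doy`, `month`.
#' @export
generate_daily_environment <- function(grid, years, params = climate_params()) {
  stopifnot(inherits(grid, "coastline_grid"), inherits(params, "climate_params"))
  if (length(years) == 0) stop("year range is empty", call. = FALSE)
  years <- as.integer(years)
  if (length(years) > 1 && any(diff(years) != 1L)) {
    stop("years must be consecutive", call. = FALSE)
  }
  n <- nrow(grid)
  for (hw in params$heatwaves) {
    if (!(hw$year %in% years)) {
      stop("heat-wave episode year ", hw$year, " outside year range",
           call. = FALSE)
    }
    if (hw$cells[1] < 0 || hw$cells[2] >= n || hw$cells[1] > hw$cells[2]) {
      stop("heat-wave episode cell range outside grid", call. = FALSE)
    }
  }

  nd_year <- .DAYS_PER_YEAR
  nd <- length(years) * nd_year
  doy <- rep.int(seq_len(nd_year), length(years))
  year <- rep(years, each = nd_year)
  month <- .MONTH_OF_DOY[doy]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(params$seed)

  seasonal <- params$seasonal_amp * cos(2 * pi * (doy - params$peak_doy) / nd_year)
  mean_lat <- params$sst_mean - params$lat_gradient * (grid$lat - params$lat_ref)
  trend <- params$trend_c_per_decade / 10 * (year - years[1])

  sst <- outer(mean_lat, rep(1, nd)) +
    matrix(seasonal + trend, n, nd, byrow = TRUE)
  # noise drawn before episodes are added, so toggling an episode leaves the
  # random stream (and hence all other days/cells) untouched
  regional <- .ar1_series(nd, params$ar_phi, params$ar_sd)
  sst <- sst + matrix(regional, n, nd, byrow = TRUE)
  if (params$cell_ar_sd > 0) {
    for (i in seq_len(n)) {
      sst[i, ] <- sst[i, ] + .ar1_series(nd, params$ar_phi, params$cell_ar_sd)
    }
  }

  swh_seasonal <- params$swh_base +
    params$swh_amp * cos(2 * pi * (doy - params$swh_peak_doy) / nd_year)
  swh <- matrix(swh_seasonal, n, nd, byrow = TRUE)
  if (params$swh_sd > 0) {
    for (i in seq_len(n)) {
      swh[i, ] <- swh[i, ] + .ar1_series(nd, params$ar_phi, params$swh_sd)
    }
  }
  swh <- pmax(swh, 0)

  if (params$wind_sd > 0) {
    wind_u <- matrix(rnorm(n * nd, 0, params$wind_sd), n, nd)
    wind_v <- matrix(rnorm(n * nd, 0, params$wind_sd), n, nd)
  } else {
    wind_u <- matrix(0, n, nd)
    wind_v <- matrix(0, n, nd)
  }
  # equatorward alongshore wind = minus the coast tangent (coast is ordered
  # equator -> pole), which drives offshore Ekman transport on this coast
  for (zone in params$upwelling_zones) {
    cells <- (zone$cells[1]:zone$cells[2]) + 1L
    if (any(cells < 1L | cells > n)) {
      stop("upwelling zone cell range outside grid", call. = FALSE)
    }
    days <- which(month %in% zone$months)
    a <- grid$coast_angle[cells] * pi / 180
    wind_u[cells, days] <- wind_u[cells, days] - zone$speed * cos(a)
    wind_v[cells, days] <- wind_v[cells, days] - zone$speed * sin(a)
    if (params$upwelling_sst_cooling != 0) {
      sst[cells, days] <- sst[cells, days] - params$upwelling_sst_cooling
    }
  }

  for (hw in params$heatwaves) {
    cells <- (hw$cells[1]:hw$cells[2]) + 1L
    d0 <- (match(hw$year, years) - 1L) * nd_year + hw$start_doy
    days <- d0:min(nd, d0 + hw$duration_days - 1L)
    sst[cells, days] <- sst[cells, days] + hw$amplitude
  }

  structure(list(
    sst = sst, swh = swh, wind_u = wind_u, wind_v = wind_v,
    year = year, doy = doy, month = month, years = years, grid = grid
  ), class = "daily_env")
}
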