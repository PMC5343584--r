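#' Physical constants for the coastal upwelling index
#'
#' Standard Bakun-convention constants for converting surface wind to
#' offshore Ekman transport per unit coastline: air density, drag
#' coefficient, seawater density, Earth's angular speed, and the length of
#' coastline the index is reported over (100 m by convention, so the index
#' is in m^3/s per 100 m of coast).
#'
#' @param rho_air air density (kg/m^3).
#' @param drag_coef dimensionless surface drag coefficient.
#' @param rho_sw seawater density (kg/m^3).
#' @param omega Earth angular speed (rad/s).
#' @param reporting_length_m coastline length the transport is reported per (m).
#' @return a `cui_params` list.
#' @export
cui_params <- function(rho_air = 1.22, drag_coef = 1.4e-3, rho_sw = 1025,
                       omega = 7.2921e-5, reporting_length_m = 100) {
  stopifnot(rho_air > 0, drag_coef > 0, rho_sw > 0, omega > 0,
            reporting_length_m > 0)
  structure(list(rho_air = rho_air, drag_coef = drag_coef, rho_sw = rho_sw,
                 omega = omega, reporting_length_m = reporting_length_m),
            class = "cui_params")
}

#' Coastal upwelling index from surface wind
#'
#' Ekman transport per unit coastline, projected on the local offshore
#' normal. Wind stress is the quadratic drag law
#' \eqn{\tau = \rho_{air} C_d |W| (u, v)}; the transport per unit width is
#' \eqn{Q = (\tau_y / (\rho_{sw} f), -\tau_x / (\rho_{sw} f))} with Coriolis
#' parameter \eqn{f = 2\Omega \sin(lat)}. The offshore normal is the coast
#' tangent rotated 90 degrees counterclockwise (ocean on the left of the
#' along-coast direction). Positive values mean offshore transport, i.e.
#' upwelling-favourable conditions.
#'
#' @param wind_u,wind_v eastward/northward wind components (m/s), vectors of
#'   equal length (e.g. one value per day).
#' @param coast_angle local coastline tangent direction, degrees
#'   counterclockwise from east.
#' @param lat latitude in degrees; must satisfy `abs(lat) > 1`.
#' @param params a [cui_params()] object.
#' @return CUI in m^3/s per `reporting_length_m` of coastline.
#' @export
compute_cui <- function(wind_u, wind_v, coast_angle, lat,
                        params = cui_params()) {
  if (abs(lat) <= 1) {
    stop("latitude within 1 degree of the equator: Coriolis parameter ",
         "ill-defined", call. = FALSE)
  }
  speed <- sqrt(wind_u^2 + wind_v^2)
  tau_x <- params$rho_air * params$drag_coef * speed * wind_u
  tau_y <- params$rho_air * params$drag_coef * speed * wind_v
  f <- 2 * params$omega * sin(lat * pi / 180)
  qx <- tau_y / (params$rho_sw * f)
  qy <- -tau_x / (params$rho_sw * f)
  an <- (coast_angle + 90) * pi / 180
  (qx * cos(an) + qy * sin(an)) * params$reporting_length_m
}

#' Is a day upwelling-favourable?
#'
#' Deep nutrient-rich water is taken to reach the surface when the coastal
#' upwelling index strictly exceeds the threshold (default 16 m^3/s per
#' 100 m of coastline).
#'
#' @param cui daily CUI value(s), m^3/s.
#' @param threshold favourability threshold, same units.
#' @return logical vector.
#' @export
favourable_upwelling_day <- function(cui, threshold = 16) {
  cui > threshold
}

#' Longest run of days strictly above a threshold
#'
#' @param series ordered daily values (may be empty).
#' @param threshold cutoff; days count when strictly above it.
#' @return integer length of the longest maximal run.
#' @export
longest_run_above <- function(series, threshold) {
  if (length(series) == 0) return(0L)
  r <- rle(series > threshold)
  hits <- r$lengths[r$values]
  if (length(hits) == 0) 0L else as.integer(max(hits))
}

.longest_true_run <- function(flags) {
  if (length(flags) == 0) return(0L)
  r <- rle(as.logical(flags))
  hits <- r$lengths[r$values]
  if (length(hits) == 0) 0L else as.integer(max(hits))
}

#' Define a season and its year-assignment rule
#'
#' A season is a month set plus the rule attaching some months to the
#' previous calendar year: the winter predictor of year t spans October to
#' December of t-1 and January-February of t, matching a life cycle in which
#' spores settle in autumn and gametophytes overwinter into the following
#' spring.
#'
#' @param name season name.
#' @param months months (1-12) belonging to the season.
#' @param prev_year_months subset of `months` drawn from calendar year t-1
#'   when computing the predictor of year t.
#' @return a `season_definition` list.
#' @export
season_definition <- function(name, months, prev_year_months = integer()) {
  months <- as.integer(months)
  prev_year_months <- as.integer(prev_year_months)
  stopifnot(length(months) > 0, !anyDuplicated(months),
            all(months %in% 1:12), all(prev_year_months %in% months))
  structure(list(name = name, months = months,
                 prev_year_months = prev_year_months),
            class = "season_definition")
}

#' Default seasons: spring MAMJ, winter ONDJF, previous summer JAS
#'
#' @return named list of [season_definition()]s.
#' @export
default_seasons <- function() {
  list(
    spring = season_definition("spring", 3:6),
    winter = season_definition("winter", c(10L, 11L, 12L, 1L, 2L),
                               prev_year_months = c(10L, 11L, 12L)),
    prev_summer = season_definition("prev_summer", 7:9,
                                    prev_year_months = 7:9)
  )
}

#' Seasonal statistics
#'
#' Constructors for the statistics applied to a season's daily values:
#' the seasonal maximum, the longest run of days strictly above a threshold,
#' and the longest run of upwelling-favourable days (CUI above a threshold).
#'
#' @param threshold cutoff in the units of the underlying variable.
#' @return a `seasonal_statistic` list.
#' @export
stat_max <- function() {
  structure(list(type = "max"), class = "seasonal_statistic")
}

#' @rdname stat_max
#' @export
stat_longest_run_above <- function(threshold) {
  structure(list(type = "longest_run_above", threshold = threshold),
            class = "seasonal_statistic")
}

#' @rdname stat_max
#' @export
stat_longest_run_favourable <- function(threshold = 16) {
  structure(list(type = "longest_run_favourable", threshold = threshold),
            class = "seasonal_statistic")
}

.apply_stat <- function(values, stat) {
  switch(stat$type,
    max = max(values),
    longest_run_above = longest_run_above(values, stat$threshold),
    longest_run_favourable =
      .longest_true_run(favourable_upwelling_day(values, stat$threshold)),
    stop("unknown seasonal statistic: ", stat$type, call. = FALSE)
  )
}

# chronological day indices of (season, target_year) within a daily series
.season_day_index <- function(year, month, season, target_year) {
  cur_months <- setdiff(season$months, season$prev_year_months)
  sel <- (year == target_year & month %in% cur_months) |
    (year == target_year - 1L & month %in% season$prev_year_months)
  idx <- which(sel)
  expected <- sum(.MONTH_DAYS[season$months])
  if (length(idx) != expected) {
    stop("incomplete season '", season$name, "' for year ", target_year,
         ": ", length(idx), " of ", expected, " days present", call. = FALSE)
  }
  idx
}

#' Apply a statistic to one season of one year of a daily series
#'
#' Selects exactly the days of `(season, target_year)` under the season's
#' year-assignment rule and applies the statistic. Errors if any day of the
#' season is missing from the series.
#'
#' @param values daily values, ordered in time.
#' @param year,month calendar year and month of each day of `values`.
#' @param season a [season_definition()].
#' @param target_year the predictor year t.
#' @param stat a `seasonal_statistic` (see [stat_max()]).
#' @return scalar statistic value.
#' @export
seasonal_stat <- function(values, year, month, season, target_year, stat) {
  stopifnot(inherits(season, "season_definition"),
            inherits(stat, "seasonal_statistic"),
            length(values) == length(year), length(values) == length(month))
  idx <- .season_day_index(year, month, season, target_year)
  .apply_stat(values[idx], stat)
}

#' Define one seasonal predictor
#'
#' @param name column name in the predictor stack.
#' @param var source variable: `"sst"`, `"swh"` or `"cui"` (derived from
#'   wind via [compute_cui()]).
#' @param season a [season_definition()].
#' @param stat a `seasonal_statistic`.
#' @return a `predictor_def` list.
#' @export
predictor_def <- function(name, var, season, stat) {
  stopifnot(var %in% c("sst", "swh", "cui"),
            inherits(season, "season_definition"),
            inherits(stat, "seasonal_statistic"))
  structure(list(name = name, var = var, season = season, stat = stat),
            class = "predictor_def")
}

#' Default predictor configuration
#'
#' The six seasonal extreme-event predictors at the core of the analysis:
#' longest runs of winter and spring days with SST above 18 degC, maximum
#' winter SST, longest run of spring upwelling-favourable days (CUI >
#' 16 m^3/s), maximum winter wave height, and longest run of spring days
#' with waves above 3 m.
#'
#' @param seasons named list from [default_seasons()].
#' @return list of [predictor_def()]s.
#' @export
default_predictor_config <- function(seasons = default_seasons()) {
  list(
    predictor_def("sst_winter_run18", "sst", seasons$winter,
                  stat_longest_run_above(18)),
    predictor_def("sst_spring_run18", "sst", seasons$spring,
                  stat_longest_run_above(18)),
    predictor_def("sst_winter_max", "sst", seasons$winter, stat_max()),
    predictor_def("cui_spring_runfav", "cui", seasons$spring,
                  stat_longest_run_favourable(16)),
    predictor_def("swh_winter_max", "swh", seasons$winter, stat_max()),
    predictor_def("swh_spring_run3", "swh", seasons$spring,
                  stat_longest_run_above(3))
  )
}

#' Monotone signs for a predictor set
#'
#' Occurrence probability is constrained to respond negatively to SST- and
#' SWH-derived predictors (heat and wave extremes harm the species) and
#' positively to CUI-derived ones (upwelling supplies nutrients).
#'
#' @param predictor_names character vector of predictor column names.
#' @return named integer vector of -1 / +1.
#' @export
default_monotone_signs <- function(predictor_names) {
  sign <- ifelse(grepl("^cui", predictor_names), 1L, -1L)
  names(sign) <- predictor_names
  sign
}

#' Build the per-cell per-year predictor stack
#'
#' Derives every configured seasonal predictor from daily environment
#' series. A pure, deterministic function of its inputs: building the stack
#' twice yields identical results.
#'
#' @param env a `daily_env` from [generate_daily_environment()].
#' @param config list of [predictor_def()]s.
#' @param years predictor years to compute; defaults to every year of the
#'   span for which all configured seasons are complete (the first year is
#'   dropped when a season reaches into the previous calendar year).
#' @param cui a [cui_params()] object.
#' @return a `predictor_stack` data.frame with columns `cell_id`, `year`
#'   and one column per predictor; predictor metadata is kept in
#'   `attr(, "predictor_meta")`.
#' @export
build_predictor_stack <- function(env, config = default_predictor_config(),
                                  years = NULL, cui = cui_params()) {
  stopifnot(inherits(env, "daily_env"))
  n <- nrow(env$grid)
  needs_prev <- any(vapply(config, function(p)
    length(p$season$prev_year_months) > 0, logical(1)))
  if (is.null(years)) {
    years <- if (needs_prev) env$years[-1] else env$years
  }
  if (length(years) == 0) stop("no complete predictor years", call. = FALSE)

  vars <- unique(vapply(config, function(p) p$var, character(1)))
  mats <- list(sst = env$sst, swh = env$swh)
  if ("cui" %in% vars) {
    cui_mat <- matrix(0, n, length(env$year))
    for (i in seq_len(n)) {
      cui_mat[i, ] <- compute_cui(env$wind_u[i, ], env$wind_v[i, ],
                                  env$grid$coast_angle[i], env$grid$lat[i],
                                  cui)
    }
    mats$cui <- cui_mat
  }

  out <- data.frame(
    cell_id = rep(env$grid$cell_id, times = length(years)),
    year = rep(as.integer(years), each = n)
  )
  for (p in config) out[[p$name]] <- NA_real_
  for (yi in seq_along(years)) {
    rows <- (yi - 1L) * n + seq_len(n)
    for (p in config) {
      idx <- .season_day_index(env$year, env$month, p$season, years[yi])
      out[rows, p$name] <-
        apply(mats[[p$var]][, idx, drop = FALSE], 1, .apply_stat, stat = p$stat)
    }
  }
  attr(out, "predictor_meta") <- lapply(config, function(p) list(
    name = p$name, var = p$var, season = p$season$name,
    stat = p$stat$type, threshold = p$stat$threshold %||% NA_real_
  ))
  class(out) <- c("predictor_stack", "data.frame")
  out
}

#' Names of the predictor columns of a stack
#' @param stack a `predictor_stack`.
#' @return character vector.
#' @export
predictor_names <- function(stack) {
  setdiff(names(stack), c("cell_id", "year"))
}
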