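#' Default synthetic coastal world
#'
#' A fully stated virtual study system mirroring the structure of a
#' warm-temperate eastern-boundary range edge over a 29-year hindcast span:
#' a 150-cell (750 km) coast, a 0.25 degC/decade warming trend, discrete
#' winter heat-wave episodes hitting the southern half of the coast in the
#' same calendar years as the region's documented marine heat waves, a
#' southern spring upwelling zone (with 2 degC surface cooling), and a
#' temperature-limited niche: a cell is suitable when the winter run of
#' days above 18 degC stays short and the winter maximum stays below the
#' gametophyte survival ceiling.
#'
#' @param seed integer seed driving every stochastic component.
#' @param n_cells number of coastal cells.
#' @param years hindcast year span.
#' @param D_true,L_true true dispersal distance (km/yr) and latency (yr) of
#'   the occupancy truth.
#' @return a list with `grid`, `params`, `env`, `stack`, `rule`, `suit`
#'   (true suitability), `truth` (true occupancy), `dist`, `D_true`,
#'   `L_true`.
#' @export
default_world <- function(seed = 1, n_cells = 150, years = 1986:2014,
                          D_true = 5, L_true = 2) {
  grid <- generate_coastline(n_cells, spacing_km = 5, seed = seed)
  south_half <- c(0L, floor(n_cells * 0.55))
  south_third <- c(0L, floor(n_cells * 0.35))
  hw_years <- intersect(c(1988:1990, 1996:1998, 2003:2004, 2006:2007), years)
  heatwaves <- lapply(seq_along(hw_years), function(k) {
    big <- k %% 2 == 1
    list(year = hw_years[k], start_doy = 300L, duration_days = 80L,
         amplitude = if (big) 2.8 else 2.2,
         cells = if (big) south_half else south_third)
  })
  params <- climate_params(
    heatwaves = heatwaves,
    upwelling_zones = list(list(cells = c(5L, floor(n_cells * 0.25)),
                                months = c(1:6, 10:12), speed = 7)),
    upwelling_sst_cooling = 2.5,
    seed = seed + 1
  )
  env <- generate_daily_environment(grid, years, params)
  stack <- build_predictor_stack(env)
  rule <- niche_rule(
    niche_condition("sst_winter_run18", "<", 25),
    niche_condition("sst_winter_max", "<", 23)
  )
  suit <- apply_niche_rule(stack, rule)
  truth <- reconstruct(suit, coastal_distance_matrix(grid),
                       reconstruction_params(D = D_true, L = L_true))
  list(grid = grid, params = params, env = env, stack = stack, rule = rule,
       suit = suit, truth = truth, dist = coastal_distance_matrix(grid),
       D_true = D_true, L_true = L_true)
}

# labeled training dataset for one survey year: presences from the records,
# pseudo-absences from the Mahalanobis + K-means background of that year
.year_training_data <- function(stack, records, year, cutoff = 0.2,
                                seed = 1) {
  xt <- stack[stack$year == year, , drop = FALSE]
  preds <- predictor_names(stack)
  rec <- records[records$year == year, , drop = FALSE]
  pres_cells <- rec$cell_id[rec$presence == 1]
  pres_idx <- match(pres_cells, xt$cell_id)
  if (length(pres_idx) == 0) {
    stop("no presences in training year ", year, call. = FALSE)
  }
  surface <- mahalanobis_suitability(xt[, preds], pres_idx)
  pa <- draw_pseudo_absences(surface, pres_idx, cutoff = cutoff, seed = seed)
  rows <- c(pres_idx, pa$rows)
  list(x = xt[rows, preds, drop = FALSE],
       y = c(rep(1L, length(pres_idx)), rep(0L, length(pa$rows))),
       presence_cells = pres_cells,
       pseudo_absence_cells = xt$cell_id[pa$rows])
}

#' Run the full analysis chain on the synthetic world
#'
#' simulate -> predictors -> pseudo-absences -> niche model
#' (transferability selection + ensemble) -> MPA-threshold binarization ->
#' dispersal-latency grid search -> evaluation, all from one seed. The
#' boosted-trees hyperparameter grid is reduced relative to the canonical
#' one to keep a desk-scale run in minutes; pass `brt_args` to widen it.
#'
#' @param seed integer global seed.
#' @param world optional pre-built [default_world()]; built from `seed`
#'   otherwise.
#' @param survey_years years surveyed (default: five recent years of the
#'   span, mirroring repeat field campaigns).
#' @param surveys_per_year survey visits per year.
#' @param train_years the two survey years used for temporal
#'   cross-validation.
#' @param rho_max pairwise Spearman bound for subset enumeration.
#' @param max_subset_size cap on enumerated subset size.
#' @param sens_min sensitivity floor of the MPA criterion.
#' @param D_range,L_range dispersal/latency search ranges.
#' @param brt_args list of arguments forwarded to [fit_brt()].
#' @return a `kelpcast_run` list collecting every stage's output:
#'   `world`, `records`, `transferability`, `selected`, `ensemble`,
#'   `prediction`, `threshold`, `suitability`, `search`, `occupancy`,
#'   `report`, `yearly`, `area`, `transitions`.
#' @export
run_pipeline <- function(seed = 1, world = NULL,
                         survey_years = NULL, surveys_per_year = 45,
                         train_years = NULL,
                         rho_max = 0.8, max_subset_size = 3,
                         sens_min = 0.9,
                         D_range = 1:50, L_range = 1:5,
                         brt_args = list(n_trees_grid = seq(100L, 300L, 50L),
                                         learning_rates = 0.01,
                                         tree_complexities = 1:2,
                                         n_folds = 5)) {
  if (is.null(world)) world <- default_world(seed)
  years <- .history_years(world$truth)
  if (is.null(survey_years)) {
    survey_years <- years[round(seq(2, length(years), length.out = 6))]
  }
  records <- sample_surveys(world$truth,
                            survey_plan(survey_years, surveys_per_year,
                                        seed = seed + 10),
                            grid = world$grid)
  if (is.null(train_years)) {
    # train on the two most presence-rich survey years (the "most complete
    # surveys"); a year needs more presences than predictors for the
    # Mahalanobis background
    pres_by_year <- vapply(survey_years, function(y)
      sum(records$presence[records$year == y]), integer(1))
    train_years <- survey_years[order(-pres_by_year)[1:2]]
  }

  train <- setNames(lapply(seq_along(train_years), function(k) {
    .year_training_data(world$stack, records, train_years[k],
                        seed = seed + 20 + k)
  }), as.character(train_years))

  subsets <- enumerate_predictor_sets(world$stack, rho_max = rho_max,
                                      max_size = max_subset_size)
  signs <- default_monotone_signs(predictor_names(world$stack))
  results <- do.call(temporal_transferability,
                     c(list(train, subsets, signs, sens_min = sens_min,
                            seed = seed + 30), brt_args))
  selected <- select_ensemble(results)

  pooled_x <- do.call(rbind, lapply(train, `[[`, "x"))
  pooled_y <- unlist(lapply(train, `[[`, "y"), use.names = FALSE)
  ensemble <- do.call(fit_ensemble,
                      c(list(selected, pooled_x, pooled_y, signs,
                             seed = seed + 40), brt_args))
  prediction <- ensemble_predict(ensemble, world$stack)

  pooled_prob <- predict_pooled(ensemble, pooled_x)
  threshold <- mpa_score(pooled_prob, pooled_y == 1, sens_min)$threshold
  suitability <- binarize(prediction, threshold)

  search <- grid_search_DL(suitability, world$dist, records,
                           D_range = D_range, L_range = L_range)
  occupancy <- reconstruct(suitability, world$dist,
                           reconstruction_params(D = search$best_D,
                                                 L = search$best_L))
  report <- confusion_stats(occupancy, records)
  structure(list(
    world = world, records = records, train = train,
    transferability = results, selected = selected, ensemble = ensemble,
    prediction = prediction, threshold = threshold,
    suitability = suitability, search = search, occupancy = occupancy,
    report = report,
    yearly = yearly_accuracy(occupancy, records),
    area = area_series(occupancy, world$grid),
    transitions = transition_map(occupancy, range(years))
  ), class = "kelpcast_run")
}

# mean ensemble probability on arbitrary labeled rows
predict_pooled <- function(ensemble, x) {
  rowMeans(vapply(ensemble, function(m) predict(m, x), numeric(nrow(x))))
}

#' @export
print.kelpcast_run <- function(x, ...) {
  cat("kelpcast pipeline run\n")
  cat(sprintf("  coast: %d cells, years %d-%d\n", nrow(x$world$grid),
              min(.history_years(x$world$truth)),
              max(.history_years(x$world$truth))))
  cat(sprintf("  records: %d (%d presences)\n", nrow(x$records),
              sum(x$records$presence)))
  cat(sprintf("  ensemble: %d model(s); MPA threshold %.3f\n",
              length(x$ensemble), x$threshold))
  cat(sprintf("  true (D, L) = (%g, %d); recovered (D, L) = (%g, %d)\n",
              x$world$D_true, x$world$L_true, x$search$best_D,
              x$search$best_L))
  cat(sprintf("  TSS %.3f (sens %.3f, spec %.3f); baseline TSS %.3f\n",
              x$report$tss, x$report$sensitivity, x$report$specificity,
              x$search$baseline_tss))
  invisible(x)
}
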