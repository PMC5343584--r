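#' Threshold niche rule
#'
#' A deterministic map from predictor values to binary habitat suitability:
#' a cell-year is suitable iff every condition holds. Used by the synthetic
#' world to define the true niche (e.g. suitable iff the winter run of days
#' above 18 degC stays short AND spring upwelling is sufficiently
#' persistent).
#'
#' @param ... conditions built with [niche_condition()].
#' @return a `niche_rule` list.
#' @export
niche_rule <- function(...) {
  conds <- list(...)
  stopifnot(all(vapply(conds, inherits, logical(1), "niche_condition")))
  structure(conds, class = "niche_rule")
}

#' @rdname niche_rule
#' @param predictor predictor column name.
#' @param op comparison operator: `"<"`, `"<="`, `">"` or `">="`.
#' @param value threshold value.
#' @export
niche_condition <- function(predictor, op, value) {
  stopifnot(op %in% c("<", "<=", ">", ">="))
  structure(list(predictor = predictor, op = op, value = value),
            class = "niche_condition")
}

#' Apply a niche rule to a predictor stack
#'
#' @param stack a `predictor_stack`.
#' @param rule a [niche_rule()].
#' @return a `suitability_history` (cells x years) covering the stack.
#' @export
apply_niche_rule <- function(stack, rule) {
  stopifnot(inherits(rule, "niche_rule"))
  ok <- rep(TRUE, nrow(stack))
  for (cond in rule) {
    if (!cond$predictor %in% names(stack)) {
      stop("predictor '", cond$predictor, "' not in stack", call. = FALSE)
    }
    ok <- ok & do.call(cond$op, list(stack[[cond$predictor]], cond$value))
  }
  cells <- sort(unique(stack$cell_id))
  years <- sort(unique(stack$year))
  suit <- matrix(0L, length(cells), length(years),
                 dimnames = list(cells, years))
  suit[cbind(match(stack$cell_id, cells), match(stack$year, years))] <-
    as.integer(ok)
  structure(suit, class = c("suitability_history", "matrix", "array"))
}

#' Simulate the true occupancy history of the synthetic world
#'
#' Ground truth for every downstream stage: the niche rule turns the
#' predictor stack into binary suitability, and the dispersal-latency
#' automaton (with the known true parameters D*, L*) turns suitability into
#' occupancy. By construction this equals
#' `reconstruct(apply_niche_rule(stack, rule), dist, params(D*, L*))`.
#'
#' @param stack a `predictor_stack`.
#' @param rule a [niche_rule()].
#' @param grid the `coastline_grid` the stack was built on.
#' @param D_true true dispersal distance (km/yr, >= 0).
#' @param L_true true latency period (years, integer >= 1).
#' @return an `occupancy_history`.
#' @export
simulate_true_occupancy <- function(stack, rule, grid, D_true, L_true) {
  if (!is.finite(D_true) || D_true < 0) stop("D_true must be >= 0", call. = FALSE)
  if (L_true < 1) stop("L_true must be >= 1", call. = FALSE)
  suit <- apply_niche_rule(stack, rule)
  reconstruct(suit, coastal_distance_matrix(grid),
              reconstruction_params(D = D_true, L = L_true))
}

#' Define a survey sampling plan
#'
#' @param years survey years.
#' @param cells_per_year number of survey visits per year; visits are drawn
#'   with replacement (repeat surveys of a cell collapse to one gridded
#'   record, mirroring how field campaigns revisit sites).
#' @param seed integer seed.
#' @return a `survey_plan` list.
#' @export
survey_plan <- function(years, cells_per_year, seed = 1) {
  if (length(years) == 0 || cells_per_year < 1) {
    stop("survey plan is empty", call. = FALSE)
  }
  structure(list(years = as.integer(years),
                 cells_per_year = as.integer(cells_per_year),
                 seed = as.integer(seed)),
            class = "survey_plan")
}

#' Sample survey records from a true occupancy history
#'
#' Perfect-detection reads of the truth at sampled (cell, year) pairs:
#' each visit reports the true presence/absence of its cell-year, and
#' duplicate visits collapse to unique gridded records (presences take
#' precedence, though with perfect detection duplicates always agree).
#'
#' @param truth an `occupancy_history`.
#' @param plan a [survey_plan()]; plan years must lie within the truth span.
#' @param grid optional `coastline_grid` used to attach lon/lat.
#' @param source tag stored in the `source` column.
#' @return an `occurrence_records` data.frame with columns `lon`, `lat`,
#'   `cell_id`, `year`, `presence`, `source`.
#' @export
sample_surveys <- function(truth, plan, grid = NULL, source = "survey") {
  stopifnot(inherits(plan, "survey_plan"))
  years <- .history_years(truth)
  if (!all(plan$years %in% years)) {
    stop("plan years outside the truth span", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(plan$seed)

  n <- nrow(truth)
  cell_ids <- rownames(truth)
  if (is.null(cell_ids)) cell_ids <- 0:(n - 1L)
  cell_ids <- as.integer(cell_ids)
  recs <- do.call(rbind, lapply(plan$years, function(y) {
    visits <- sample.int(n, plan$cells_per_year, replace = TRUE)
    data.frame(cell_id = cell_ids[visits], year = y,
               presence = truth[visits, match(y, years)])
  }))
  recs <- .collapse_records(recs)
  recs$source <- source
  if (!is.null(grid)) {
    m <- match(recs$cell_id, grid$cell_id)
    recs <- data.frame(lon = grid$lon[m], lat = grid$lat[m], recs)
  }
  rownames(recs) <- NULL
  class(recs) <- c("occurrence_records", "data.frame")
  recs
}
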