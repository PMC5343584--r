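#' Confusion statistics of a reconstruction against occurrence records
#'
#' Pools every record over space and time, compares it with the
#' reconstructed occupancy at its (cell, year), and derives sensitivity
#' (true presence rate), specificity (true absence rate) and the True Skill
#' Statistic TSS = sensitivity + specificity - 1, ranging -1 to +1.
#'
#' @param occ an `occupancy_history`.
#' @param records data.frame with `cell_id`, `year`, `presence`; duplicate
#'   cell-years collapse with presence precedence.
#' @param allow_undefined if `FALSE` (default), records lacking one of the
#'   two classes raise an undefined-rate error; if `TRUE`, the affected
#'   rate (and TSS) is reported as `NA`.
#' @return an `evaluation_report` list with `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `tss`, `n_records`.
#' @export
confusion_stats <- function(occ, records, allow_undefined = FALSE) {
  rec <- .collapse_records(records)
  years <- .history_years(occ)
  if (!all(rec$year %in% years)) {
    stop("records outside the occupancy span", call. = FALSE)
  }
  cell_ids <- rownames(occ)
  ri <- if (is.null(cell_ids)) rec$cell_id + 1L
        else match(rec$cell_id, cell_ids)
  if (anyNA(ri) || any(ri < 1L) || any(ri > nrow(occ))) {
    stop("record cell_id outside grid", call. = FALSE)
  }
  pred <- occ[cbind(ri, match(rec$year, years))]
  tp <- sum(pred == 1 & rec$presence == 1)
  fn <- sum(pred == 0 & rec$presence == 1)
  tn <- sum(pred == 0 & rec$presence == 0)
  fp <- sum(pred == 1 & rec$presence == 0)
  if (!allow_undefined && (tp + fn == 0 || tn + fp == 0)) {
    stop("records contain no ",
         if (tp + fn == 0) "presences: sensitivity" else "absences: specificity",
         " undefined", call. = FALSE)
  }
  sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = sens, specificity = spec,
                 tss = sens + spec - 1, n_records = nrow(rec)),
            class = "evaluation_report")
}

#' Per-year accuracy of a reconstruction
#'
#' One confusion report per year holding at least one record (undefined
#' rates reported as `NA` when a year has only one class); years without
#' records are marked empty.
#'
#' @inheritParams confusion_stats
#' @return data.frame with one row per year of the occupancy span: `year`,
#'   `n_records`, `tp`, `fp`, `tn`, `fn`, `sensitivity`, `specificity`,
#'   `tss` (all `NA` for empty years).
#' @export
yearly_accuracy <- function(occ, records) {
  rec <- .collapse_records(records)
  years <- .history_years(occ)
  out <- data.frame(year = years, n_records = 0L, tp = NA_integer_,
                    fp = NA_integer_, tn = NA_integer_, fn = NA_integer_,
                    sensitivity = NA_real_, specificity = NA_real_,
                    tss = NA_real_)
  for (k in seq_along(years)) {
    ry <- rec[rec$year == years[k], , drop = FALSE]
    if (nrow(ry) == 0) next
    rep_y <- confusion_stats(occ, ry, allow_undefined = TRUE)
    out[k, c("n_records", "tp", "fp", "tn", "fn")] <-
      c(rep_y$n_records, rep_y$tp, rep_y$fp, rep_y$tn, rep_y$fn)
    out$sensitivity[k] <- rep_y$sensitivity
    out$specificity[k] <- rep_y$specificity
    out$tss[k] <- rep_y$tss
  }
  out
}

#' Occupied area through time
#'
#' @param occ an `occupancy_history`.
#' @param grid the `coastline_grid` (supplies per-cell area in km^2).
#' @param reference_year year the percent change is computed against
#'   (default: first year of the span).
#' @return data.frame with `year`, `n_cells`, `area_km2`, `pct_change`.
#' @export
area_series <- function(occ, grid, reference_year = NULL) {
  years <- .history_years(occ)
  area <- colSums(occ * grid$cell_area)
  n_cells <- colSums(occ == 1)
  if (is.null(reference_year)) reference_year <- years[1]
  ref <- area[match(reference_year, years)]
  pct <- if (is.na(ref) || ref == 0) rep(NA_real_, length(area))
         else 100 * (area - ref) / ref
  data.frame(year = years, n_cells = as.integer(n_cells),
             area_km2 = as.numeric(area), pct_change = as.numeric(pct))
}

#' Classify per-cell fate within a period
#'
#' Partitions the cells into mutually exclusive classes over a year
#' interval: `never_present` (no presence year), `persistence` (present at
#' the end with no absence gap after first colonization), `extinction`
#' (present at some year but absent in the period's final year) and
#' `extinction_then_recolonization` (an internal absence gap between
#' presences, present again at the end).
#'
#' @param occ an `occupancy_history`.
#' @param period length-2 year interval `c(from, to)` within the span.
#' @return data.frame with `cell_id` and `class` (factor over the four
#'   classes).
#' @export
transition_map <- function(occ, period) {
  years <- .history_years(occ)
  stopifnot(length(period) == 2, period[1] <= period[2])
  if (!all(period %in% years)) stop("period outside occupancy span",
                                    call. = FALSE)
  cols <- which(years >= period[1] & years <= period[2])
  if (length(cols) == 0) stop("empty period", call. = FALSE)
  sub <- occ[, cols, drop = FALSE]
  classify <- function(x) {
    pres <- which(x == 1)
    if (length(pres) == 0) return("never_present")
    final <- x[length(x)] == 1
    gap <- length(pres) > 1 && any(diff(pres) > 1)
    if (!final) return("extinction")
    if (gap) return("extinction_then_recolonization")
    "persistence"
  }
  cls <- apply(sub, 1, classify)
  cell_ids <- rownames(occ)
  if (is.null(cell_ids)) cell_ids <- 0:(nrow(occ) - 1L)
  data.frame(
    cell_id = as.integer(cell_ids),
    class = factor(cls, levels = c("persistence", "extinction",
                                   "extinction_then_recolonization",
                                   "never_present"))
  )
}
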