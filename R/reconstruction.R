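#' Reconstruction parameters: dispersal distance and latency period
#'
#' The occupancy automaton is controlled by a yearly dispersal distance D
#' (km: the maximum along-coast range over which a presence at year t-1 can
#' rescue a suitable cell at year t) and a latency period L (years: how far
#' back a cell's own former presence can re-found a population, e.g. via
#' dormant microscopic stages). Three modes mirror the three reconstruction
#' types: `no_dispersal` (permanent absence once unsuitable; D = 0, L = 1),
#' `unlimited` (occupancy equals suitability) and `explicit` (finite D, L).
#'
#' @param D dispersal distance in km/yr (explicit mode; >= 0).
#' @param L latency period in years (explicit mode; integer >= 1).
#' @param mode one of `"explicit"`, `"no_dispersal"`, `"unlimited"`.
#' @return a `reconstruction_params` list.
#' @export
reconstruction_params <- function(D = NULL, L = NULL,
                                  mode = c("explicit", "no_dispersal",
                                           "unlimited")) {
  mode <- match.arg(mode)
  if (mode == "explicit") {
    if (is.null(D) || !is.finite(D) || D < 0) {
      stop("explicit mode requires finite D >= 0", call. = FALSE)
    }
    if (is.null(L) || L < 1 || L != as.integer(L)) {
      stop("explicit mode requires integer L >= 1", call. = FALSE)
    }
    L <- as.integer(L)
  }
  structure(list(D = D, L = L, mode = mode), class = "reconstruction_params")
}

.as_binary_matrix <- function(x) {
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  stopifnot(all(m %in% c(0L, 1L)))
  m
}

#' Binary suitability history from ensemble probabilities
#'
#' @param pred cells x years matrix of occurrence probabilities (an
#'   `ensemble_prediction`), with year column names.
#' @param threshold probability cutoff in (0, 1]; a cell-year is suitable
#'   iff its probability is `>= threshold` (typically the MPA threshold).
#' @return a `suitability_history` binary matrix (cells x years).
#' @export
binarize <- function(pred, threshold) {
  if (!is.numeric(threshold) || threshold <= 0 || threshold > 1) {
    stop("threshold must be in (0, 1]", call. = FALSE)
  }
  m <- as.matrix(pred)
  suit <- (m >= threshold) * 1L
  storage.mode(suit) <- "integer"
  dimnames(suit) <- dimnames(m)
  structure(suit, threshold = threshold,
            class = c("suitability_history", "matrix", "array"))
}

#' Construct a suitability history from a binary matrix
#'
#' @param mat cells x years binary matrix; column names are years.
#' @param years optional year vector for column names.
#' @return a `suitability_history`.
#' @export
suitability_history <- function(mat, years = NULL) {
  m <- .as_binary_matrix(mat)
  if (!is.null(years)) colnames(m) <- years
  structure(m, class = c("suitability_history", "matrix", "array"))
}

.history_years <- function(h) {
  cn <- colnames(h)
  if (is.null(cn)) seq_len(ncol(h)) else as.integer(cn)
}

#' Reconstruct occupancy through time from binary suitability
#'
#' The dispersal-latency automaton. The first year is seeded with the
#' suitability map itself. For every later year t, a suitable cell i is
#' occupied iff (1) it was occupied in any of the previous L years
#' (latency: persistence through dormant stages), or (2) some other cell
#' within D km along the coast was occupied at t-1 (rescue / colonization).
#' Unsuitable cells are never occupied.
#'
#' @param suit a `suitability_history` (cells x years binary matrix).
#' @param dist along-coast distance matrix from [coastal_distance_matrix()]
#'   (ignored in `unlimited` mode).
#' @param params a [reconstruction_params()].
#' @param latency_window if `TRUE` (default) the latency condition looks at
#'   every year in `{t-1, ..., t-L}`; if `FALSE`, only at exactly `t-L`.
#' @return an `occupancy_history` binary matrix with the same dimensions.
#' @export
reconstruct <- function(suit, dist = NULL, params, latency_window = TRUE) {
  stopifnot(inherits(params, "reconstruction_params"))
  suit_m <- .as_binary_matrix(suit)
  if (ncol(suit_m) < 1) stop("suitability spans no years", call. = FALSE)
  occ <- switch(params$mode,
    unlimited = suit_m,
    no_dispersal = occupancy_automaton_cpp(
      suit_m, matrix(0, nrow(suit_m), nrow(suit_m)), -1, 1L, TRUE),
    explicit = {
      if (is.null(dist)) stop("explicit mode needs a distance matrix",
                              call. = FALSE)
      stopifnot(nrow(dist) == nrow(suit_m))
      occupancy_automaton_cpp(suit_m, as.matrix(dist), params$D, params$L,
                              latency_window)
    })
  dimnames(occ) <- dimnames(suit_m)
  structure(occ, class = c("occupancy_history", "matrix", "array"))
}

# collapse duplicate (cell, year) records; presences take precedence over
# absences when sources disagree
.collapse_records <- function(records) {
  stopifnot(all(c("cell_id", "year", "presence") %in% names(records)))
  stopifnot(all(records$presence %in% c(0, 1)))
  agg <- stats::aggregate(presence ~ cell_id + year, data = records, FUN = max)
  agg[order(agg$year, agg$cell_id), , drop = FALSE]
}

#' Grid search over dispersal distance and latency period
#'
#' Reconstructs occupancy for every (D, L) combination, scores each
#' reconstruction against all occurrence records pooled over space and
#' time with the True Skill Statistic, and reports the marginal TSS over a
#' no-dispersal/no-latency baseline. The best combination maximizes TSS;
#' ties break toward smaller L, then smaller D (parsimony).
#'
#' @param suit a `suitability_history`.
#' @param dist along-coast distance matrix.
#' @param records data.frame with `cell_id`, `year`, `presence` (0/1);
#'   duplicates collapse with presence precedence. Must contain both
#'   presences and absences within the reconstruction span.
#' @param D_range,L_range candidate dispersal distances (km) and latency
#'   periods (years); defaults 1:500 and 1:5 give the canonical 2500
#'   candidate reconstructions.
#' @param baseline `"no_dispersal"` (D = 0, L = 1; default) or `"L0"`
#'   (additionally no year-to-year persistence).
#' @param latency_window see [reconstruct()].
#' @return list with `best_D`, `best_L`, `best_tss`, `baseline_tss`, and
#'   `surface`: a data.frame over the full grid with columns `D`, `L`,
#'   `tss`, `marginal_tss`.
#' @export
grid_search_DL <- function(suit, dist, records, D_range = 1:500,
                           L_range = 1:5, baseline = c("no_dispersal", "L0"),
                           latency_window = TRUE) {
  baseline <- match.arg(baseline)
  suit_m <- .as_binary_matrix(suit)
  years <- .history_years(suit_m)
  rec <- .collapse_records(records)
  if (!all(rec$year %in% years)) {
    stop("records outside the reconstruction year span", call. = FALSE)
  }
  if (all(rec$presence == 1)) {
    stop("records contain no absences: TSS undefined", call. = FALSE)
  }
  if (all(rec$presence == 0)) {
    stop("records contain no presences: TSS undefined", call. = FALSE)
  }
  cell_ids <- rownames(suit_m)
  rec_i <- if (is.null(cell_ids)) rec$cell_id else match(rec$cell_id, cell_ids) - 1L
  if (is.null(cell_ids) && (any(rec$cell_id < 0) ||
                            any(rec$cell_id >= nrow(suit_m)))) {
    stop("record cell_id outside grid", call. = FALSE)
  }
  rec_t <- match(rec$year, years) - 1L

  base_L <- if (baseline == "no_dispersal") 1L else 0L
  base_occ <- occupancy_automaton_cpp(
    suit_m, matrix(0, nrow(suit_m), nrow(suit_m)), -1, base_L, latency_window)
  base_tss <- .tss_from_occ(base_occ, rec_i, rec_t, rec$presence)

  tss <- tss_surface_cpp(suit_m, as.matrix(dist), as.numeric(D_range),
                         as.integer(L_range), as.integer(rec_i),
                         as.integer(rec_t), as.integer(rec$presence),
                         latency_window)
  surface <- data.frame(
    D = rep(D_range, times = length(L_range)),
    L = rep(L_range, each = length(D_range)),
    tss = as.numeric(tss)
  )
  surface$marginal_tss <- surface$tss - base_tss
  ord <- order(-surface$tss, surface$L, surface$D)
  best <- surface[ord[1], ]
  list(best_D = best$D, best_L = best$L, best_tss = best$tss,
       baseline_tss = base_tss, surface = surface)
}

.tss_from_occ <- function(occ, rec_i, rec_t, pres) {
  pred <- occ[cbind(rec_i + 1L, rec_t + 1L)]
  tp <- sum(pred == 1 & pres == 1); fn <- sum(pred == 0 & pres == 1)
  tn <- sum(pred == 0 & pres == 0); fp <- sum(pred == 1 & pres == 0)
  tp / (tp + fn) + tn / (tn + fp) - 1
}
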