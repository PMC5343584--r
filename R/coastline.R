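#' Generate a one-dimensional synthetic coastline
#'
#' Builds an ordered chain of coastal cells (the spatial substrate for the
#' whole pipeline): consecutive `cell_id`s `0..n-1` in along-coast order,
#' geographic coordinates, a smoothly varying coastline tangent angle, and a
#' fixed along-coast spacing between adjacent cells. The chain topology
#' realizes "shortest path along the coast" distances exactly.
#'
#' The coast is laid out roughly south-to-north (an eastern-ocean-margin
#' analogue such as western Iberia), so the alongshore equatorward direction
#' is minus the tangent.
#'
#' @param n_cells number of cells (>= 2).
#' @param spacing_km along-coast distance between adjacent cells (km);
#'   default 5 km, matching a 0.05 degree coastal grid.
#' @param seed integer seed controlling the smooth angle wiggle.
#' @param cell_width_km assumed cross-shore width of a cell (km), used only
#'   for `cell_area`.
#' @param lon0,lat0 coordinates of the first (southernmost) cell.
#' @return a `coastline_grid` data.frame with columns `cell_id`, `lon`,
#'   `lat`, `coast_angle` (degrees counterclockwise from east of the local
#'   tangent), `cell_size` (degrees), `cell_area` (km^2), plus attributes
#'   `spacing_km` and `pos_km` (cumulative along-coast position).
#' @export
generate_coastline <- function(n_cells, spacing_km = 5, seed = 1,
                               cell_width_km = 5, lon0 = -9.0, lat0 = 36.0) {
  if (!is.numeric(n_cells) || n_cells < 2) {
    stop("n_cells must be >= 2", call. = FALSE)
  }
  if (spacing_km <= 0) stop("spacing_km must be > 0", call. = FALSE)
  n_cells <- as.integer(n_cells)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  # tangent angle: northward (90 deg) plus a smoothed random walk, bounded so
  # the coast never folds back on itself
  wiggle <- cumsum(rnorm(n_cells, 0, 2))
  if (n_cells >= 5) {
    wiggle <- stats::filter(wiggle, rep(1 / 5, 5), sides = 2)
    wiggle[is.na(wiggle)] <- 0
  }
  angle <- 90 + pmin(40, pmax(-40, as.numeric(wiggle)))

  lon <- numeric(n_cells); lat <- numeric(n_cells)
  lon[1] <- lon0; lat[1] <- lat0
  for (i in seq_len(n_cells - 1L)) {
    a <- angle[i] * pi / 180
    lat[i + 1] <- lat[i] + spacing_km * sin(a) / 111.32
    lon[i + 1] <- lon[i] + spacing_km * cos(a) / (111.32 * cos(lat[i] * pi / 180))
  }

  grid <- data.frame(
    cell_id = 0:(n_cells - 1L),
    lon = lon, lat = lat,
    coast_angle = angle,
    cell_size = 0.05,
    cell_area = spacing_km * cell_width_km
  )
  attr(grid, "spacing_km") <- spacing_km
  attr(grid, "pos_km") <- spacing_km * (0:(n_cells - 1L))
  class(grid) <- c("coastline_grid", "data.frame")
  grid
}

#' Along-coast shortest-path distance matrix
#'
#' Distances between every pair of cells along the coastal chain, in km.
#' Symmetric with a zero diagonal; on a chain the shortest path is the
#' cumulative along-coast position difference.
#'
#' @param grid a `coastline_grid`.
#' @return an n x n numeric matrix (km).
#' @export
coastal_distance_matrix <- function(grid) {
  stopifnot(inherits(grid, "coastline_grid"))
  pos <- attr(grid, "pos_km")
  if (is.null(pos)) pos <- attr(grid, "spacing_km") * (seq_len(nrow(grid)) - 1)
  abs(outer(pos, pos, "-"))
}

# Save/restore .Random.seed so seeded generators do not clobber the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
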