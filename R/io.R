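#' Read and write occurrence records as CSV
#'
#' Plain-text exchange format with header
#' `lon,lat,cell_id,year,presence,source`.
#'
#' @param records an `occurrence_records` data.frame.
#' @param path CSV file path.
#' @return `read_records_csv` returns an `occurrence_records` data.frame.
#' @export
write_records_csv <- function(records, path) {
  cols <- intersect(c("lon", "lat", "cell_id", "year", "presence", "source"),
                    names(records))
  write.csv(as.data.frame(records)[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  rec <- read.csv(path)
  stopifnot(all(c("cell_id", "year", "presence") %in% names(rec)))
  class(rec) <- c("occurrence_records", "data.frame")
  rec
}

#' Read and write binary cell-by-year histories as CSV
#'
#' Wide layout: first column `cell_id`, one column per year. Used for both
#' suitability and occupancy histories.
#'
#' @param history a `suitability_history` or `occupancy_history`.
#' @param path CSV file path.
#' @param class_out class to restore on read (`"occupancy_history"` or
#'   `"suitability_history"`).
#' @return `read_history_csv` returns the binary matrix with the requested
#'   class.
#' @export
write_history_csv <- function(history, path) {
  df <- data.frame(cell_id = rownames(history) %||% (0:(nrow(history) - 1L)),
                   as.data.frame(unclass(history), check.names = FALSE))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history_csv
#' @export
read_history_csv <- function(path, class_out = "occupancy_history") {
  df <- read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$cell_id
  structure(m, class = c(class_out, "matrix", "array"))
}

#' Write a predictor stack as CSV
#'
#' Long layout: `cell_id`, `year`, one column per predictor.
#'
#' @param stack a `predictor_stack`.
#' @param path CSV file path.
#' @return `read_stack_csv` returns a `predictor_stack`.
#' @export
write_stack_csv <- function(stack, path) {
  write.csv(as.data.frame(stack), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  stack <- read.csv(path)
  stopifnot(all(c("cell_id", "year") %in% names(stack)))
  class(stack) <- c("predictor_stack", "data.frame")
  stack
}

#' Persist a model registry as JSON lines
#'
#' One JSON object per selected model: predictor subset, monotone signs,
#' tuned hyperparameters and mean MPA.
#'
#' @param results selected rows of a `transferability_result`.
#' @param ensemble matching `kelp_ensemble` (supplies hyperparameters).
#' @param path output file.
#' @export
write_model_registry <- function(results, ensemble, path) {
  lines <- vapply(seq_len(nrow(results)), function(i) {
    spec <- ensemble[[i]]$spec
    jsonlite::toJSON(list(
      predictors = spec$predictors,
      monotone = unname(spec$monotone),
      n_trees = spec$n_trees,
      learning_rate = spec$learning_rate,
      tree_complexity = spec$tree_complexity,
      bag_fraction = spec$bag_fraction,
      mean_mpa = results$mean_mpa[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
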