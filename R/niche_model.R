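#' Enumerate weakly correlated predictor subsets
#'
#' All non-empty subsets of the stack's predictors in which every pair has
#' pairwise Spearman correlation `|R| < rho_max`, computed over all
#' cell-years. Fitting one model per subset reduces over-parameterization
#' and provides the basis for per-predictor contribution scores.
#'
#' @param stack a `predictor_stack` (or data.frame of predictor columns).
#' @param rho_max strict pairwise correlation bound (default 0.8).
#' @param max_size cap on subset size to bound the 2^p enumeration.
#' @return list of character vectors (predictor subsets), smaller subsets
#'   first.
#' @export
enumerate_predictor_sets <- function(stack, rho_max = 0.8, max_size = 8) {
  preds <- if (inherits(stack, "predictor_stack")) predictor_names(stack)
           else colnames(stack)
  if (length(preds) < 1) stop("no predictors", call. = FALSE)
  if (length(preds) > 16) {
    stop("too many predictors to enumerate (", length(preds), ")",
         call. = FALSE)
  }
  rho <- suppressWarnings(
    cor(as.data.frame(stack)[, preds, drop = FALSE], method = "spearman"))
  rho[is.na(rho)] <- 0
  ok_pair <- abs(rho) < rho_max
  out <- list()
  for (size in seq_len(min(length(preds), max_size))) {
    for (idx in as.data.frame(combn(length(preds), size))) {
      if (size == 1 || all(ok_pair[idx, idx][upper.tri(diag(size))])) {
        out[[length(out) + 1L]] <- preds[idx]
      }
    }
  }
  out
}

#' Minimum Predicted Area at a sensitivity floor
#'
#' The transferability criterion: the threshold is the largest probability
#' cutoff at which at least `sens_min` of the test presences are still
#' predicted present, and the MPA is the fraction of all test cells at or
#' above that threshold. Lower MPA = a model that honours the presences
#' with a smaller predicted area = more parsimonious and transferable.
#'
#' @param probabilities predicted occurrence probability per test cell.
#' @param presence_idx indices (or logical vector) of test presences.
#' @param sens_min required sensitivity (default 0.9).
#' @return list with `threshold` and `mpa`.
#' @export
mpa_score <- function(probabilities, presence_idx, sens_min = 0.9) {
  if (is.logical(presence_idx)) presence_idx <- which(presence_idx)
  n_pres <- length(presence_idx)
  if (n_pres < 1) stop("no test presences", call. = FALSE)
  need <- ceiling(sens_min * n_pres)
  threshold <- sort(probabilities[presence_idx], decreasing = TRUE)[need]
  list(threshold = threshold, mpa = mean(probabilities >= threshold))
}

#' Temporal cross-validation of candidate predictor subsets
#'
#' Fits each candidate subset on one year's labeled data and scores the MPA
#' on the other year's, in both directions (and over all ordered pairs when
#' more than two years are given). A subset's transferability score is its
#' mean MPA over directions; the most transferable subsets are those with
#' the lowest mean MPA.
#'
#' @param year_data named list (length >= 2) of labeled datasets, each a
#'   list with `x` (data.frame of predictor columns) and `y` (0/1).
#' @param subsets list of predictor subsets (from
#'   [enumerate_predictor_sets()]).
#' @param monotone named signs covering every predictor used.
#' @param sens_min sensitivity floor for the MPA.
#' @param seed integer seed (forwarded to [fit_brt()]).
#' @param ... further arguments to [fit_brt()] (hyperparameter grids).
#' @return a `transferability_result` data.frame with `label`, `mean_mpa`,
#'   a list-column `predictors`, and per-direction MPAs in
#'   `attr(, "directions")`.
#' @export
temporal_transferability <- function(year_data, subsets, monotone,
                                     sens_min = 0.9, seed = 1, ...) {
  stopifnot(length(year_data) >= 2)
  for (nm in names(year_data)) {
    if (sum(year_data[[nm]]$y == 1) < 1) {
      stop("year dataset '", nm, "' has no presences", call. = FALSE)
    }
  }
  pairs <- expand.grid(train = names(year_data), test = names(year_data),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$train != pairs$test, , drop = FALSE]
  dir_mpa <- matrix(NA_real_, length(subsets), nrow(pairs),
                    dimnames = list(NULL, paste(pairs$train, pairs$test,
                                                sep = "->")))
  for (s in seq_along(subsets)) {
    sub <- subsets[[s]]
    for (d in seq_len(nrow(pairs))) {
      tr <- year_data[[pairs$train[d]]]
      te <- year_data[[pairs$test[d]]]
      fit <- fit_brt(tr$x[, sub, drop = FALSE], tr$y, monotone[sub],
                     seed = seed, ...)
      prob <- predict(fit, te$x[, sub, drop = FALSE])
      dir_mpa[s, d] <- mpa_score(prob, te$y == 1, sens_min)$mpa
    }
  }
  out <- data.frame(
    label = vapply(subsets, paste, character(1), collapse = "+"),
    mean_mpa = rowMeans(dir_mpa)
  )
  out$predictors <- subsets
  attr(out, "directions") <- dir_mpa
  class(out) <- c("transferability_result", "data.frame")
  out
}

#' Select the most transferable models
#'
#' Keeps the subsets whose mean MPA falls within the lowest decile of the
#' observed mean-MPA range (ties at the minimum always included); an
#' absolute tolerance above the minimum can be supplied instead.
#'
#' @param results a `transferability_result`.
#' @param tol optional absolute tolerance above the minimum mean MPA,
#'   overriding the decile rule.
#' @return the selected rows of `results`, best first.
#' @export
select_ensemble <- function(results, tol = NULL) {
  stopifnot(nrow(results) >= 1)
  mpa <- results$mean_mpa
  cutoff <- if (is.null(tol)) min(mpa) + (max(mpa) - min(mpa)) / 10
            else min(mpa) + tol
  sel <- results[mpa <= cutoff, , drop = FALSE]
  sel[order(sel$mean_mpa), , drop = FALSE]
}

#' Refit selected subsets on pooled training data
#'
#' @param selected rows of a `transferability_result` (from
#'   [select_ensemble()]).
#' @param x,y pooled labeled training data over all training years.
#' @param monotone named signs covering every predictor used.
#' @param seed integer seed.
#' @param ... further arguments to [fit_brt()].
#' @return a `kelp_ensemble`: list of fitted `kelp_brt_fit` members.
#' @export
fit_ensemble <- function(selected, x, y, monotone, seed = 1, ...) {
  members <- lapply(selected$predictors, function(sub) {
    fit_brt(x[, sub, drop = FALSE], y, monotone[sub], seed = seed, ...)
  })
  structure(members, class = "kelp_ensemble")
}

#' Ensemble habitat-suitability prediction
#'
#' Per (cell, year) arithmetic mean of member probabilities, assigned on a
#' yearly basis to the predictor stack.
#'
#' @param ensemble a `kelp_ensemble` (or a list of fitted members).
#' @param stack a `predictor_stack` covering every member's predictors.
#' @return an `ensemble_prediction`: cells x years probability matrix.
#' @export
ensemble_predict <- function(ensemble, stack) {
  stopifnot(length(ensemble) >= 1)
  for (m in ensemble) {
    missing <- setdiff(m$spec$predictors, names(stack))
    if (length(missing) > 0) {
      stop("stack lacks predictor(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  probs <- vapply(ensemble, function(m) predict(m, stack),
                  numeric(nrow(stack)))
  prob <- rowMeans(as.matrix(probs))
  cells <- sort(unique(stack$cell_id))
  years <- sort(unique(stack$year))
  out <- matrix(NA_real_, length(cells), length(years),
                dimnames = list(cells, years))
  out[cbind(match(stack$cell_id, cells), match(stack$year, years))] <- prob
  structure(out, class = c("ensemble_prediction", "matrix", "array"))
}

.subset_key <- function(sub) paste(sort(sub), collapse = "|")

#' Per-predictor contribution scores
#'
#' Scores each predictor's contribution to model transferability and
#' rescales the vector to sum to 100. Two operationalizations are exposed:
#' `"reduction"` (default) averages the drop in mean MPA over every paired
#' comparison between a subset without the predictor and the same subset
#' with it; `"one_minus_mpa"` transforms the mean MPA of all subsets
#' containing the predictor as 1 - MPA. Higher = stronger contribution.
#'
#' @param results a `transferability_result` covering all enumerated
#'   subsets.
#' @param method `"reduction"` or `"one_minus_mpa"`.
#' @return named numeric vector summing to 100.
#' @export
predictor_contributions <- function(results,
                                    method = c("reduction",
                                               "one_minus_mpa")) {
  method <- match.arg(method)
  subsets <- results$predictors
  mpa <- results$mean_mpa
  keys <- vapply(subsets, .subset_key, character(1))
  preds <- sort(unique(unlist(subsets)))
  score <- setNames(numeric(length(preds)), preds)
  for (p in preds) {
    if (method == "one_minus_mpa") {
      has_p <- vapply(subsets, function(s) p %in% s, logical(1))
      if (!any(has_p)) {
        stop("contribution undefined for '", p, "': in no subset",
             call. = FALSE)
      }
      score[p] <- 1 - mean(mpa[has_p])
    } else {
      without <- which(vapply(subsets, function(s) !(p %in% s), logical(1)))
      drops <- numeric(0)
      for (m in without) {
        k <- match(.subset_key(c(subsets[[m]], p)), keys)
        if (!is.na(k)) drops <- c(drops, mpa[m] - mpa[k])
      }
      if (length(drops) == 0) {
        stop("contribution undefined for '", p, "': never addable",
             call. = FALSE)
      }
      score[p] <- mean(drops)
    }
  }
  total <- sum(score)
  if (total <= 0) {
    stop("non-positive total contribution score: cannot rescale",
         call. = FALSE)
  }
  100 * score / total
}
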