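#' Fit a single boosted regression tree model
#'
#' Bernoulli gradient boosting with per-feature monotone constraints,
#' the learner behind [fit_brt()]. Trees are grown on Newton gradients;
#' splits on a constrained feature must order the child values according to
#' the constraint sign, and node bounds are propagated down the tree so the
#' fitted function is monotone in every constrained feature.
#'
#' @param x matrix or data.frame of predictors.
#' @param y binary response (0/1).
#' @param monotone named integer vector of -1/0/+1 per predictor (order or
#'   names matching `x`).
#' @param n_trees number of boosting iterations.
#' @param learning_rate shrinkage applied to each tree.
#' @param tree_depth maximum interaction depth of each tree.
#' @param bag_fraction per-iteration subsample proportion.
#' @param min_obs minimum observations per leaf.
#' @param seed integer seed for the stochastic subsampling.
#' @param valid_x,valid_y optional holdout set; holdout deviance is then
#'   recorded at `checkpoints` (tree counts).
#' @param checkpoints increasing tree counts at which deviance is recorded.
#' @return a `kelp_brt` model.
#' @export
brt <- function(x, y, monotone, n_trees = 1000, learning_rate = 0.01,
                tree_depth = 1, bag_fraction = 0.5, min_obs = 10, seed = 1,
                valid_x = NULL, valid_y = NULL,
                checkpoints = integer(0)) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.integer(y)
  stopifnot(all(y %in% c(0L, 1L)), nrow(x) == length(y))
  if (length(unique(y)) < 2) {
    stop("training data contains a single class", call. = FALSE)
  }
  if (!is.null(names(monotone)) && !is.null(colnames(x))) {
    monotone <- monotone[colnames(x)]
  }
  stopifnot(length(monotone) == ncol(x), all(monotone %in% -1:1))
  if (is.null(valid_x)) {
    valid_x <- matrix(0, 0, ncol(x))
    valid_y <- integer(0)
  } else {
    valid_x <- as.matrix(valid_x)
    storage.mode(valid_x) <- "double"
    valid_y <- as.integer(valid_y)
  }
  checkpoints <- sort(unique(as.integer(checkpoints)))
  fit <- brt_fit_cpp(x, y, as.integer(monotone), as.integer(n_trees),
                     learning_rate, as.integer(tree_depth), bag_fraction,
                     as.integer(min_obs), as.integer(seed),
                     valid_x, valid_y, checkpoints)
  structure(list(
    trees = fit$trees, init = fit$init, shrinkage = learning_rate,
    n_trees = as.integer(n_trees), tree_depth = as.integer(tree_depth),
    bag_fraction = bag_fraction, monotone = monotone,
    predictors = colnames(x), checkpoints = checkpoints,
    train_deviance = fit$train_deviance, valid_deviance = fit$valid_deviance
  ), class = "kelp_brt")
}

#' Predict from a boosted-trees model
#'
#' @param object a `kelp_brt`.
#' @param newdata matrix or data.frame containing the model's predictors.
#' @param n_trees number of trees to use (default: all).
#' @param type `"response"` for probabilities, `"link"` for log-odds.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.kelp_brt <- function(object, newdata, n_trees = NULL,
                             type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (!is.null(object$predictors)) {
    missing <- setdiff(object$predictors, colnames(as.data.frame(newdata)))
    if (length(missing) > 0) {
      stop("missing predictor column(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    newdata <- as.data.frame(newdata)[, object$predictors, drop = FALSE]
  }
  xm <- as.matrix(newdata)
  storage.mode(xm) <- "double"
  link <- brt_predict_cpp(object$trees, object$init, xm, object$shrinkage,
                          if (is.null(n_trees)) object$n_trees
                          else as.integer(n_trees))
  if (type == "link") link else plogis(link)
}

#' Tune and fit a monotone boosted-trees niche model
#'
#' Hyperparameters are selected by k-fold cross-validation on the training
#' data, minimizing mean holdout Bernoulli deviance over the grid of tree
#' counts (100 to 10000, step 50), learning rates (0.01, 0.005, 0.001) and
#' tree complexities (1 up to the number of predictors); the bag fraction
#' is fixed at 0.5. Tree counts are evaluated as checkpoints of a single
#' boosting run per (learning rate, complexity, fold), then the model is
#' refit on the full training data at the winning combination.
#'
#' The canonical grid is large; tests and small studies pass reduced
#' `n_trees_grid`/`learning_rates`. Values outside the canonical grid are
#' rejected unless `allow_custom_grid = TRUE`.
#'
#' @param x data.frame/matrix of predictors (training rows: presences and
#'   pseudo-absences).
#' @param y binary response.
#' @param monotone named signs per predictor (-1/0/+1).
#' @param n_trees_grid candidate tree counts.
#' @param learning_rates candidate learning rates.
#' @param tree_complexities candidate interaction depths (default
#'   `1:ncol(x)`).
#' @param bag_fraction subsample proportion (default 0.5).
#' @param n_folds cross-validation folds (default 10).
#' @param min_obs minimum observations per leaf.
#' @param seed integer seed (folds and subsampling).
#' @param allow_custom_grid allow values outside the canonical grid.
#' @return a `kelp_brt_fit`: the refit `model` plus a `spec` recording the
#'   subset, signs, chosen hyperparameters and CV deviance.
#' @export
fit_brt <- function(x, y, monotone,
                    n_trees_grid = seq(100L, 10000L, 50L),
                    learning_rates = c(0.01, 0.005, 0.001),
                    tree_complexities = NULL,
                    bag_fraction = 0.5, n_folds = 10, min_obs = 10,
                    seed = 1, allow_custom_grid = FALSE) {
  x <- as.data.frame(x)
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("training data contains a single class", call. = FALSE)
  }
  p <- ncol(x)
  if (is.null(tree_complexities)) tree_complexities <- seq_len(p)
  if (!allow_custom_grid) {
    canonical_nt <- seq(100L, 10000L, 50L)
    if (!all(n_trees_grid %in% canonical_nt)) {
      stop("n_trees_grid outside the canonical 100..10000 step-50 grid ",
           "(set allow_custom_grid = TRUE to override)", call. = FALSE)
    }
    if (!all(learning_rates %in% c(0.01, 0.005, 0.001))) {
      stop("learning rate outside {0.01, 0.005, 0.001} ",
           "(set allow_custom_grid = TRUE to override)", call. = FALSE)
    }
  }
  stopifnot(all(tree_complexities >= 1))
  # complexity cannot exceed the number of predictors in the subset
  tree_complexities <- tree_complexities[tree_complexities <= p]
  if (length(tree_complexities) == 0) tree_complexities <- p
  n_trees_grid <- sort(unique(as.integer(n_trees_grid)))
  max_trees <- max(n_trees_grid)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n <- nrow(x)
  n_folds <- max(2L, min(as.integer(n_folds), n))
  fold <- sample(rep_len(seq_len(n_folds), n))

  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  best <- list(dev = Inf)
  for (lr in learning_rates) {
    for (depth in tree_complexities) {
      cv_dev <- matrix(NA_real_, n_folds, length(n_trees_grid))
      for (f in seq_len(n_folds)) {
        tr <- fold != f
        if (length(unique(y[tr])) < 2 || sum(!tr) == 0) next
        m <- brt(xm[tr, , drop = FALSE], y[tr], monotone,
                 n_trees = max_trees, learning_rate = lr, tree_depth = depth,
                 bag_fraction = bag_fraction, min_obs = min_obs,
                 seed = seed + f,
                 valid_x = xm[!tr, , drop = FALSE], valid_y = y[!tr],
                 checkpoints = n_trees_grid)
        cv_dev[f, ] <- m$valid_deviance
      }
      mean_dev <- colMeans(cv_dev, na.rm = TRUE)
      k <- which.min(mean_dev)
      if (length(k) == 1 && mean_dev[k] < best$dev) {
        best <- list(dev = mean_dev[k], n_trees = n_trees_grid[k],
                     learning_rate = lr, tree_depth = depth,
                     cv_curve = mean_dev)
      }
    }
  }
  if (!is.finite(best$dev)) {
    stop("cross-validation failed on every fold", call. = FALSE)
  }
  model <- brt(xm, y, monotone, n_trees = best$n_trees,
               learning_rate = best$learning_rate,
               tree_depth = best$tree_depth, bag_fraction = bag_fraction,
               min_obs = min_obs, seed = seed)
  structure(list(
    model = model,
    spec = list(predictors = colnames(x), monotone = monotone,
                n_trees = best$n_trees, learning_rate = best$learning_rate,
                tree_complexity = best$tree_depth,
                bag_fraction = bag_fraction, cv_deviance = best$dev)
  ), class = "kelp_brt_fit")
}

#' @export
predict.kelp_brt_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}
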