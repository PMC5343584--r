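test_that("predictor-set enumeration filters correlated pairs", {
  set.seed(8)
  n <- 200
  a <- rnorm(n); b <- rnorm(n); c_ <- rnorm(n)
  uncorrelated <- data.frame(cell_id = 1:n, year = 2000, a = a, b = b, c = c_)
  class(uncorrelated) <- c("predictor_stack", "data.frame")
  expect_length(enumerate_predictor_sets(uncorrelated), 7)  # 2^3 - 1

  # |rho(a, b)| ~ 1, everything else weak
  strong <- data.frame(cell_id = 1:n, year = 2000, a = a, b = a + 0.01 * b,
                       c = c_)
  class(strong) <- c("predictor_stack", "data.frame")
  sets <- enumerate_predictor_sets(strong)
  keys <- vapply(sets, paste, character(1), collapse = "+")
  expect_setequal(keys, c("a", "b", "c", "a+c", "b+c"))

  single <- data.frame(cell_id = 1:n, year = 2000, a = a)
  class(single) <- c("predictor_stack", "data.frame")
  expect_length(enumerate_predictor_sets(single), 1)
  # max_size caps enumeration
  expect_true(all(lengths(enumerate_predictor_sets(uncorrelated,
                                                   max_size = 1)) == 1))
})

test_that("MPA threshold honours the sensitivity floor", {
  # perfect separation
  prob <- c(rep(1, 3), rep(0, 7))
  m <- mpa_score(prob, 1:3)
  expect_equal(m$threshold, 1.0)
  expect_equal(m$mpa, 3 / 10)
  # worked six-cell example: ceil(0.9 * 4) = 4 presences required
  m2 <- mpa_score(c(0.9, 0.8, 0.7, 0.2, 0.1, 0.05), 1:4)
  expect_equal(m2$threshold, 0.2)
  expect_equal(m2$mpa, 4 / 6)
  # uniform probabilities cover everything
  expect_equal(mpa_score(rep(0.4, 12), c(2, 5))$mpa, 1.0)
  expect_error(mpa_score(prob, integer(0)), "presences")
  # MPA is monotone non-increasing as sens_min decreases
  set.seed(1)
  p <- runif(50); pres <- sample(50, 20)
  mpas <- vapply(c(0.95, 0.9, 0.7, 0.5), function(s)
    mpa_score(p, pres, s)$mpa, numeric(1))
  expect_true(all(diff(mpas) <= 1e-12))
})

test_that("ensemble selection keeps the lowest-MPA decile and ties", {
  res <- data.frame(label = c("m1", "m2", "m3"),
                    mean_mpa = c(0.2, 0.21, 0.8))
  res$predictors <- list("a", "b", "c")
  class(res) <- c("transferability_result", "data.frame")
  expect_equal(select_ensemble(res)$label, c("m1", "m2"))
  res$mean_mpa <- c(0.3, 0.3, 0.9)
  expect_equal(sort(select_ensemble(res)$label), c("m1", "m2"))
  one <- res[1, , drop = FALSE]
  expect_equal(select_ensemble(one)$label, "m1")
})

test_that("ensemble prediction averages members per cell-year", {
  set.seed(21)
  x <- data.frame(a = runif(120, 0, 10))
  y <- as.integer(x$a < 5)
  stack <- data.frame(cell_id = rep(0:19, 3), year = rep(2001:2003, each = 20),
                      a = runif(60, 0, 10))
  class(stack) <- c("predictor_stack", "data.frame")
  f1 <- fit_brt(x, y, c(a = -1L), n_trees_grid = seq(100, 200, 50),
                learning_rates = 0.01, n_folds = 5, seed = 1)
  f2 <- fit_brt(x, y, c(a = -1L), n_trees_grid = seq(100, 200, 50),
                learning_rates = 0.01, n_folds = 5, seed = 2)
  e12 <- ensemble_predict(structure(list(f1, f2), class = "kelp_ensemble"),
                          stack)
  e21 <- ensemble_predict(structure(list(f2, f1), class = "kelp_ensemble"),
                          stack)
  e11 <- ensemble_predict(structure(list(f1, f1), class = "kelp_ensemble"),
                          stack)
  single <- ensemble_predict(structure(list(f1), class = "kelp_ensemble"),
                             stack)
  expect_equal(e12, e21)                       # member-order invariance
  expect_equal(e11, single)                    # identical members
  p1 <- predict(f1, stack); p2 <- predict(f2, stack)
  got <- e12[cbind(match(stack$cell_id, sort(unique(stack$cell_id))),
                   match(stack$year, 2001:2003))]
  expect_equal(got, (p1 + p2) / 2)             # plain mean
  # bounded by member min/max
  expect_true(all(got >= pmin(p1, p2) - 1e-12 & got <= pmax(p1, p2) + 1e-12))
  bad <- stack; names(bad)[3] <- "z"
  expect_error(ensemble_predict(structure(list(f1), class = "kelp_ensemble"),
                                bad), "lacks predictor")
})

test_that("predictor contributions rescale to 100 under both methods", {
  res <- data.frame(label = c("a", "b", "a+b"),
                    mean_mpa = c(0.3, 0.9, 0.5))
  res$predictors <- list("a", "b", c("a", "b"))
  class(res) <- c("transferability_result", "data.frame")
  # 1 - mean MPA of subsets containing p: a -> 1 - 0.4 = 0.6, b -> 0.3
  cb <- predictor_contributions(res, method = "one_minus_mpa")
  expect_equal(unname(cb), c(200 / 3, 100 / 3), tolerance = 1e-9)
  expect_equal(sum(cb), 100, tolerance = 1e-9)
  # paired reduction: a: MPA({b}) - MPA({a,b}) = 0.4; b: 0.3 - 0.5 = -0.2
  cr <- predictor_contributions(res, method = "reduction")
  expect_equal(sum(cr), 100, tolerance = 1e-9)
  expect_gt(cr["a"], cr["b"])
  # equal MPA everywhere -> equal split
  res$mean_mpa <- rep(0.5, 3)
  expect_equal(unname(predictor_contributions(res, "one_minus_mpa")),
               c(50, 50))
  # a predictor present in no addable pair errors under "reduction"
  res2 <- data.frame(label = c("a", "b"), mean_mpa = c(0.2, 0.4))
  res2$predictors <- list("a", "b")
  class(res2) <- c("transferability_result", "data.frame")
  expect_error(predictor_contributions(res2, "reduction"), "never addable")
})

test_that("temporal transferability is symmetric on identical years and ranks", {
  y1 <- separable_year(200, seed = 31)
  d1 <- label_from_truth(y1, n_pres = 40, seed = 31)
  res <- do.call(temporal_transferability,
                 c(list(list(A = d1, B = d1), list("a", c("a", "b")),
                        c(a = -1L, b = 1L), seed = 5), small_brt_args))
  dir <- attr(res, "directions")
  expect_equal(dir[, 1], dir[, 2])             # identical datasets
  expect_equal(res$mean_mpa, rowMeans(dir))
  expect_equal(select_ensemble(res)$label[1],
               res$label[which.min(res$mean_mpa)])
  bad <- d1; bad$y <- rep(0L, length(bad$y))
  expect_error(temporal_transferability(list(A = bad, B = d1), list("a"),
                                        c(a = -1L)), "no presences")
})

test_that("a pure-noise predictor earns the lowest contribution", {
  wins <- 0L
  for (r in 1:10) {
    y1 <- separable_year(220, seed = 600 + r)
    y2 <- separable_year(220, seed = 700 + r)
    set.seed(800 + r)
    y1$x$noise <- runif(220); y2$x$noise <- runif(220)
    d1 <- label_from_truth(y1, n_pres = 40, seed = 600 + r)
    d2 <- label_from_truth(y2, n_pres = 40, seed = 700 + r)
    subsets <- list("a", "noise", c("a", "noise"))
    res <- do.call(temporal_transferability,
                   c(list(list(A = d1, B = d2), subsets,
                          c(a = -1L, noise = 0L), seed = r),
                     small_brt_args))
    cb <- predictor_contributions(res, method = "one_minus_mpa")
    if (which.min(cb) == match("noise", names(cb))) wins <- wins + 1L
  }
  expect_gte(wins, 8L)
})
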