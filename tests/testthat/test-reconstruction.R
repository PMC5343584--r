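test_that("binarize thresholds probabilities inclusively", {
  pred <- matrix(c(0.3, 0.7, 1.0, 0.5), 2, 2,
                 dimnames = list(0:1, 2001:2002))
  expect_equal(as.vector(unclass(binarize(pred, 0.5))), c(0L, 1L, 1L, 1L))
  expect_equal(as.vector(unclass(binarize(pred, 1.0))), c(0L, 0L, 1L, 0L))
  expect_error(binarize(pred, 0), "threshold")
  expect_error(binarize(pred, 1.2), "threshold")
  # lowering the threshold never shrinks the suitable set
  set.seed(2)
  p <- matrix(runif(60), 10, 6)
  for (th in c(0.9, 0.6, 0.3)) {
    expect_true(all(binarize(p, th) >= binarize(p, min(1, th + 0.2))))
  }
})

test_that("reconstruction params validate their domain", {
  expect_error(reconstruction_params(D = -1, L = 1), "D >= 0")
  expect_error(reconstruction_params(D = 5, L = 0), "L >= 1")
  expect_error(reconstruction_params(D = 5, L = 1.5), "L >= 1")
  expect_s3_class(reconstruction_params(mode = "unlimited"),
                  "reconstruction_params")
})

test_that("hand-traced automaton recurrences", {
  d1 <- matrix(0, 1, 1)
  s <- suitability_history(matrix(c(1, 0, 1, 1), 1), years = 2001:2004)
  expect_equal(as.vector(reconstruct(s, d1, reconstruction_params(D = 0, L = 1))),
               c(1, 0, 0, 0))
  expect_equal(as.vector(reconstruct(s, d1, reconstruction_params(D = 0, L = 2))),
               c(1, 0, 1, 1))
  # two adjacent cells 5 km apart: rescue radius inclusive at D = 5
  sAB <- suitability_history(rbind(c(1, 1, 1), c(0, 1, 1)))
  dAB <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_equal(reconstruct(sAB, dAB, reconstruction_params(D = 5, L = 1))[2, ],
               c(0, 1, 1))
  expect_equal(reconstruct(sAB, dAB, reconstruction_params(D = 4, L = 1))[2, ],
               c(0, 0, 0))
  # unlimited mode: occupancy is a direct function of suitability
  expect_equal(unclass(reconstruct(sAB, params = reconstruction_params(mode = "unlimited"))),
               unclass(sAB), ignore_attr = TRUE)
  # no-dispersal mode: permanent absence once unsuitable
  sx <- suitability_history(matrix(c(1, 0, 1, 1, 1, 1), 2, 3))
  expect_equal(as.vector(reconstruct(sx, params = reconstruction_params(mode = "no_dispersal"))),
               c(1, 0, 1, 0, 1, 0))
})

test_that("automaton matches the brute-force oracle on random instances", {
  for (seed in 1:60) {
    inst <- random_instance(seed)
    D <- runif(1, 0, 30); L <- sample(1:5, 1)
    got <- reconstruct(suitability_history(inst$suit), inst$dist,
                       reconstruction_params(D = D, L = L))
    expect_identical(unclass(got),
                     oracle_reconstruct(inst$suit, inst$dist, D, L),
                     info = paste("seed", seed))
  }
})

test_that("occupancy is nested in suitability and monotone in (D, L)", {
  for (seed in 101:130) {
    inst <- random_instance(seed)
    s <- suitability_history(inst$suit)
    D <- runif(1, 0, 20); L <- sample(1:4, 1)
    occ <- reconstruct(s, inst$dist, reconstruction_params(D = D, L = L))
    occ_big <- reconstruct(s, inst$dist,
                           reconstruction_params(D = D + 10, L = L + 1))
    nod <- reconstruct(s, params = reconstruction_params(mode = "no_dispersal"))
    unl <- reconstruct(s, params = reconstruction_params(mode = "unlimited"))
    expect_true(all(occ <= inst$suit))
    expect_true(all(occ <= occ_big))
    expect_true(all(nod <= occ))
    expect_true(all(occ <= unl))
  }
})

test_that("grid search recovers self-consistent parameters with parsimony ties", {
  set.seed(77)
  n <- 40; nT <- 12
  suit <- suitability_history(matrix(rbinom(n * nT, 1, 0.6), n, nT),
                              years = 2001:2012)
  pos <- 5 * (0:(n - 1)); dist <- abs(outer(pos, pos, "-"))
  truth <- reconstruct(suit, dist, reconstruction_params(D = 5, L = 2))
  recs <- data.frame(
    cell_id = rep(0:(n - 1), nT), year = rep(2001:2012, each = n),
    presence = as.vector(truth))
  gs <- grid_search_DL(suit, dist, recs, D_range = 1:30, L_range = 1:5)
  expect_equal(nrow(gs$surface), 150)
  expect_equal(gs$best_tss, 1)
  expect_equal(gs$surface$tss[gs$surface$D == 5 & gs$surface$L == 2], 1)
  # tie-break is parsimonious: no (D, L) below the winner also attains 1
  winners <- gs$surface[gs$surface$tss == 1, ]
  expect_true(all(winners$L >= gs$best_L))
  expect_equal(gs$best_D,
               min(winners$D[winners$L == gs$best_L]))
  # marginal TSS relative to the no-dispersal baseline
  expect_equal(gs$surface$marginal_tss, gs$surface$tss - gs$baseline_tss)
})

test_that("grid search validates its records", {
  s <- suitability_history(matrix(1L, 3, 3), years = 1:3)
  d <- matrix(0, 3, 3)
  pres_only <- data.frame(cell_id = 0, year = 1, presence = 1)
  expect_error(grid_search_DL(s, d, pres_only), "no absences")
  abs_only <- data.frame(cell_id = 0, year = 1, presence = 0)
  expect_error(grid_search_DL(s, d, abs_only), "no presences")
  outside <- data.frame(cell_id = 0, year = 9, presence = c(0, 1))
  expect_error(grid_search_DL(s, d, outside), "outside")
})
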