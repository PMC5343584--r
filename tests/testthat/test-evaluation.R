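occ_fixture <- function() {
  structure(matrix(c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L), 2, 4,
                   dimnames = list(0:1, 2001:2004)),
            class = c("occupancy_history", "matrix", "array"))
}

test_that("confusion statistics and the TSS identity", {
  occ <- occ_fixture()
  perfect <- data.frame(cell_id = rep(0:1, 4), year = rep(2001:2004, each = 2),
                        presence = as.vector(occ))
  rep1 <- confusion_stats(occ, perfect)
  expect_equal(rep1$sensitivity, 1)
  expect_equal(rep1$specificity, 1)
  expect_equal(rep1$tss, 1)
  expect_equal(rep1$n_records, 8)

  # prediction independent of truth: all-present occupancy has TSS 0
  all1 <- structure(matrix(1L, 2, 4, dimnames = dimnames(occ)),
                    class = class(occ))
  rep0 <- confusion_stats(all1, perfect)
  expect_equal(rep0$tss, 0)

  # identity sens + spec - 1 to 1e-12 on random confusion data
  set.seed(12)
  for (k in 1:25) {
    n <- 60
    occ_r <- structure(matrix(rbinom(n, 1, 0.5), 10, 6,
                              dimnames = list(0:9, 2001:2006)),
                       class = class(occ))
    rec <- data.frame(cell_id = sample(0:9, n, TRUE),
                      year = sample(2001:2006, n, TRUE),
                      presence = rbinom(n, 1, 0.5))
    r <- confusion_stats(occ_r, rec, allow_undefined = TRUE)
    if (!is.na(r$tss)) {
      expect_equal(r$tss, r$sensitivity + r$specificity - 1,
                   tolerance = 1e-12)
    }
  }
  expect_error(confusion_stats(occ, perfect[perfect$presence == 1, ]),
               "no absences")
  expect_error(confusion_stats(occ, data.frame(cell_id = 0, year = 1990,
                                               presence = 1)), "span")
})

test_that("duplicate records collapse with presence precedence", {
  occ <- occ_fixture()
  rec <- data.frame(cell_id = c(0, 0, 1), year = c(2001, 2001, 2001),
                    presence = c(0, 1, 0))
  r <- confusion_stats(occ, rec)
  expect_equal(r$n_records, 2)           # (0, 2001) collapsed
  expect_equal(r$tp, 1)                  # presence wins the conflict
})

test_that("yearly accuracy partitions the pooled counts", {
  occ <- occ_fixture()
  set.seed(3)
  rec <- data.frame(cell_id = sample(0:1, 30, TRUE),
                    year = sample(2001:2003, 30, TRUE),
                    presence = rbinom(30, 1, 0.5))
  rec <- rec[!duplicated(rec[c("cell_id", "year")]), ]
  yearly <- yearly_accuracy(occ, rec)
  pooled <- confusion_stats(occ, rec, allow_undefined = TRUE)
  expect_equal(sum(yearly$tp, na.rm = TRUE), pooled$tp)
  expect_equal(sum(yearly$fn, na.rm = TRUE), pooled$fn)
  expect_equal(sum(yearly$n_records, na.rm = TRUE), pooled$n_records)
  expect_equal(yearly$n_records[yearly$year == 2004], 0L)  # empty year

  # a presence-only year reports sensitivity but flags specificity NA
  one <- yearly_accuracy(occ, data.frame(cell_id = 0, year = 2001,
                                         presence = 1))
  row <- one[one$year == 2001, ]
  expect_equal(row$sensitivity, 1)
  expect_true(is.na(row$specificity))
})

test_that("area series is linear in cell area", {
  g <- tiny_grid(10)
  g$cell_area <- 25
  occ <- structure(matrix(0L, 10, 3, dimnames = list(0:9, 2001:2003)),
                   class = c("occupancy_history", "matrix", "array"))
  occ[1:10, 1] <- 1L
  occ[1:5, 2] <- 1L
  a <- area_series(occ, g)
  expect_equal(a$area_km2, c(250, 125, 0))
  expect_equal(a$pct_change, c(0, -50, -100))
  g2 <- g; g2$cell_area <- 50
  expect_equal(area_series(occ, g2)$area_km2, 2 * a$area_km2)
})

test_that("transition classes partition the cells", {
  traj <- rbind(c(1, 1, 1, 1),   # persistence
                c(1, 1, 0, 0),   # extinction
                c(1, 0, 1, 1),   # extinction then recolonization
                c(0, 0, 0, 0),   # never present
                c(0, 0, 1, 1),   # late colonization, no gap -> persistence
                c(1, 0, 1, 0))   # gap but absent at the end -> extinction
  occ <- structure(apply(traj, 2, as.integer),
                   class = c("occupancy_history", "matrix", "array"))
  dimnames(occ) <- list(0:5, 2001:2004)
  tm <- transition_map(occ, c(2001, 2004))
  expect_equal(as.character(tm$class),
               c("persistence", "extinction", "extinction_then_recolonization",
                 "never_present", "persistence", "extinction"))
  expect_false(anyNA(tm$class))
  expect_error(transition_map(occ, c(1990, 1991)), "outside")
  # a sub-period reclassifies consistently
  tm2 <- transition_map(occ, c(2001, 2002))
  expect_equal(as.character(tm2$class[1]), "persistence")
  expect_equal(as.character(tm2$class[3]), "extinction")
})

test_that("CSV round trips preserve records, histories and stacks", {
  tmp <- tempfile("kelpcast-io-")
  dir.create(tmp)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)
  occ <- occ_fixture()
  f1 <- file.path(tmp, "occ.csv")
  write_history_csv(occ, f1)
  expect_equal(unclass(read_history_csv(f1)), unclass(occ),
               ignore_attr = TRUE)

  rec <- data.frame(lon = c(-9, -9.1), lat = c(38, 38.1), cell_id = 0:1,
                    year = c(2001L, 2002L), presence = c(1L, 0L),
                    source = "survey")
  f2 <- file.path(tmp, "rec.csv")
  write_records_csv(rec, f2)
  back <- read_records_csv(f2)
  expect_equal(as.data.frame(back), rec)

  g <- tiny_grid(3)
  env <- generate_daily_environment(g, 2000:2001, quiet_params())
  stack <- build_predictor_stack(env)
  f3 <- file.path(tmp, "stack.csv")
  write_stack_csv(stack, f3)
  back_s <- read_stack_csv(f3)
  expect_equal(as.data.frame(back_s)[predictor_names(stack)],
               as.data.frame(stack)[predictor_names(stack)])
})
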