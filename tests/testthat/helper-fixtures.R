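# quiet climate: no noise, no trend, no episodes — SST is an exact sinusoid
quiet_params <- function(...) {
  args <- utils::modifyList(
    list(trend_c_per_decade = 0, ar_sd = 0, cell_ar_sd = 0,
         wind_sd = 0, swh_sd = 0),
    list(...))
  do.call(climate_params, args)
}

tiny_grid <- function(n = 5, spacing = 5, seed = 1) {
  generate_coastline(n, spacing_km = spacing, seed = seed)
}

# small labeled dataset with a known separable niche (presence iff a < 5,
# and b > 3 when two-sided); used by the niche-model tests
separable_year <- function(n = 250, seed = 1) {
  set.seed(seed)
  x <- data.frame(a = runif(n, 0, 10), b = runif(n, 0, 10))
  list(x = x, suit = x$a < 5 & x$b > 3)
}

label_from_truth <- function(yr, n_pres = 45, seed = 1) {
  set.seed(seed)
  pres <- sample(which(yr$suit), n_pres)
  surf <- mahalanobis_suitability(yr$x, pres)
  pa <- draw_pseudo_absences(surf, pres, seed = seed)
  list(x = yr$x[c(pres, pa$rows), ],
       y = rep(1:0, c(n_pres, length(pa$rows))))
}

small_brt_args <- list(n_trees_grid = seq(100L, 300L, 50L),
                       learning_rates = 0.01, tree_complexities = 1:2,
                       n_folds = 5)
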