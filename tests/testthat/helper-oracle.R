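# Independent brute-force oracle for the occupancy automaton: re-derives
# each year by literal evaluation of the latency and rescue conditions over
# all cell pairs and all lag years. Deliberately naive; kept free of any
# package internals.
oracle_reconstruct <- function(suit, dist, D, L, latency_window = TRUE) {
  n <- nrow(suit); nT <- ncol(suit)
  occ <- matrix(0L, n, nT)
  occ[, 1] <- suit[, 1]
  if (nT < 2) return(occ)
  for (t in 2:nT) {
    for (i in 1:n) {
      if (suit[i, t] == 0) next
      latent <- FALSE
      if (L >= 1) {
        taus <- if (latency_window) seq(t - 1, max(1, t - L)) else t - L
        taus <- taus[taus >= 1]
        for (tau in taus) if (occ[i, tau] == 1) latent <- TRUE
      }
      rescued <- FALSE
      for (j in 1:n) {
        if (j != i && occ[j, t - 1] == 1 && dist[i, j] <= D) rescued <- TRUE
      }
      if (latent || rescued) occ[i, t] <- 1L
    }
  }
  occ
}

# random automaton instance on a chain
random_instance <- function(seed, max_cells = 10, max_years = 10) {
  set.seed(seed)
  n <- sample(2:max_cells, 1)
  nT <- sample(2:max_years, 1)
  spacing <- sample(1:6, 1)
  pos <- spacing * (0:(n - 1))
  list(
    suit = matrix(rbinom(n * nT, 1, runif(1, 0.2, 0.8)), n, nT),
    dist = abs(outer(pos, pos, "-")),
    n = n, years = nT
  )
}

oracle_tss <- function(pred, obs) {
  sens <- mean(pred[obs == 1] == 1)
  spec <- mean(pred[obs == 0] == 0)
  sens + spec - 1
}
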