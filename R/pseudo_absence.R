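#' Mahalanobis habitat-suitability surface
#'
#' Relates the normalized environmental predictors to the presence records:
#' predictors are z-scored over all cells, the presence cells define a
#' centroid and covariance, and each cell's squared Mahalanobis distance to
#' the centroid is mapped to a suitability probability through the upper
#' tail of the chi-square distribution with df = number of predictors
#' (suitability 1 exactly at the centroid).
#'
#' @param x matrix or data.frame of predictor values, one row per cell.
#' @param presence_idx integer row indices (or logical vector) of presence
#'   cells.
#' @return a `suitability_surface` data.frame with columns `row`, `d2` and
#'   `suitability`; normalization and centroid statistics are kept as
#'   attributes.
#' @export
mahalanobis_suitability <- function(x, presence_idx) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.logical(presence_idx)) presence_idx <- which(presence_idx)
  p <- ncol(x)
  if (length(presence_idx) <= p) {
    stop("need more presence rows than predictors (", length(presence_idx),
         " <= ", p, ")", call. = FALSE)
  }
  mu_all <- colMeans(x)
  sd_all <- apply(x, 2, sd)
  if (any(sd_all == 0)) {
    stop("constant predictor column: cannot normalize", call. = FALSE)
  }
  z <- scale(x, center = mu_all, scale = sd_all)
  zp <- z[presence_idx, , drop = FALSE]
  mu <- colMeans(zp)
  sigma <- stats::cov(zp)
  ok <- tryCatch({solve(sigma); TRUE}, error = function(e) FALSE)
  if (!ok || !is.finite(rcond <- rcond(sigma)) || rcond < 1e-12) {
    stop("degenerate presence covariance (singular or near-singular)",
         call. = FALSE)
  }
  d2 <- mahalanobis(z, center = mu, cov = sigma)
  out <- data.frame(row = seq_len(nrow(x)), d2 = d2,
                    suitability = 1 - pchisq(d2, df = p))
  attr(out, "normalization") <- list(center = mu_all, scale = sd_all)
  attr(out, "centroid") <- mu
  attr(out, "df") <- p
  attr(out, "z") <- z
  class(out) <- c("suitability_surface", "data.frame")
  out
}

#' Draw pseudo-absences by K-means stratification of dissimilar cells
#'
#' Training absences are drawn from outside the species' ecological space:
#' cells with Mahalanobis suitability at or below the cutoff (default 0.2),
#' excluding presence cells, are clustered by K-means on the normalized
#' predictors with k equal to the number of presence records, and one cell
#' is drawn uniformly at random from each cluster — so the pseudo-absence
#' count always equals the presence count.
#'
#' Empty or merged clusters (K-means can return fewer occupied clusters than
#' k when eligible cells are few or duplicated) are topped up by drawing
#' additional distinct cells from the largest clusters.
#'
#' @param surface a [mahalanobis_suitability()] result for the same rows.
#' @param presence_idx presence row indices (or logical).
#' @param cutoff suitability cutoff (inclusive) for eligibility.
#' @param seed integer seed for clustering and the per-cluster draw.
#' @return a `pseudo_absence_set` list with `rows` (selected row indices),
#'   `cluster` assignments, `cutoff` and `seed`.
#' @export
draw_pseudo_absences <- function(surface, presence_idx, cutoff = 0.2,
                                 seed = 1) {
  stopifnot(inherits(surface, "suitability_surface"))
  if (is.logical(presence_idx)) presence_idx <- which(presence_idx)
  n_pres <- length(presence_idx)
  if (n_pres < 1) stop("no presence rows", call. = FALSE)
  eligible <- setdiff(surface$row[surface$suitability <= cutoff], presence_idx)
  if (length(eligible) < n_pres) {
    stop("insufficient background: ", length(eligible),
         " eligible cells for ", n_pres, " presences", call. = FALSE)
  }
  z <- attr(surface, "z")[eligible, , drop = FALSE]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  if (length(eligible) == n_pres) {
    sel <- eligible
    cl <- seq_len(n_pres)
  } else {
    km <- NULL
    for (attempt in 1:10) {
      km <- tryCatch(
        suppressWarnings(kmeans(z, centers = n_pres, iter.max = 50,
                                nstart = 1, algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(km)) break
    }
    if (is.null(km)) {
      stop("K-means failed on the eligible background", call. = FALSE)
    }
    cl_assign <- km$cluster
    sel <- integer(0)
    for (k in sort(unique(cl_assign))) {
      members <- eligible[cl_assign == k]
      sel <- c(sel, members[sample.int(length(members), 1L)])
    }
    # top up if some clusters came back empty
    while (length(sel) < n_pres) {
      counts <- table(cl_assign)
      biggest <- as.integer(names(counts)[which.max(counts)])
      pool <- setdiff(eligible[cl_assign == biggest], sel)
      if (length(pool) == 0) pool <- setdiff(eligible, sel)
      sel <- c(sel, pool[sample.int(length(pool), 1L)])
    }
    cl <- cl_assign[match(sel, eligible)]
  }
  structure(list(rows = sel, cluster = cl, cutoff = cutoff, seed = seed),
            class = "pseudo_absence_set")
}
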