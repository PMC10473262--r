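#' Empirical variogram of a parcellated brain map
#'
#' For parcel pairs binned by centroid distance, the variogram is half the
#' mean squared value difference per bin:
#' \eqn{\gamma(d) = \frac{1}{2} E[(v_i - v_j)^2]} over pairs at distance d.
#' Pairs beyond the `max_dist_quantile` quantile of pairwise distances are
#' ignored (long-distance bins are sparse and unstable).
#'
#' @param values per-parcel numeric map.
#' @param geometry a [parcel_geometry()].
#' @param n_bins number of equal-width distance bins.
#' @param max_dist_quantile distance cap as a quantile of pairwise
#'   distances.
#' @return tibble of class `variogram` with `distance` (bin centers),
#'   `gamma`, `n_pairs`; empty bins are dropped with their count recorded
#'   as 0 in the `dropped_bins` attribute.
#' @export
empirical_variogram <- function(values, geometry, n_bins = 25,
                                max_dist_quantile = 0.5) {
  stopifnot(inherits(geometry, "parcel_geometry"))
  if (length(values) != nrow(geometry$distance)) {
    stop("Map length does not match geometry.", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("Map must be finite.", call. = FALSE)
  pr <- variogram_pairs(geometry, n_bins, max_dist_quantile)
  gamma_binned(values, pr)
}

# Precompute pair indices (sorted by bin), bin boundaries and centers for a
# geometry so repeated variogram evaluations (surrogate fitting) are cheap.
variogram_pairs <- function(geometry, n_bins = 25, max_dist_quantile = 0.5) {
  d <- geometry$distance
  np <- nrow(d)
  ut <- upper.tri(d)
  dist_vec <- d[ut]
  dmax <- stats::quantile(dist_vec, max_dist_quantile)
  keep <- dist_vec <= dmax
  idx <- which(ut, arr.ind = TRUE)[keep, , drop = FALSE]
  dist_vec <- dist_vec[keep]
  breaks <- seq(0, dmax, length.out = n_bins + 1L)
  bin <- pmin(pmax(findInterval(dist_vec, breaks, rightmost.closed = TRUE),
                   1L), n_bins)
  ord <- order(bin)
  counts <- tabulate(bin, nbins = n_bins)
  centers <- (breaks[-1] + breaks[-length(breaks)]) / 2
  list(i = idx[ord, 1], j = idx[ord, 2], counts = counts,
       ends = cumsum(counts), centers = centers, n_bins = n_bins)
}

# Per-bin variogram values as a bare numeric vector (NaN for empty bins);
# cumulative-sum trick keeps this O(pairs) with no grouping overhead.
gamma_vec <- function(values, pr) {
  sq <- 0.5 * (values[pr$i] - values[pr$j])^2
  csx <- c(0, cumsum(sq))
  prev <- c(0L, pr$ends[-pr$n_bins])
  (csx[pr$ends + 1L] - csx[prev + 1L]) / pr$counts
}

gamma_binned <- function(values, pr) {
  g <- gamma_vec(values, pr)
  present <- pr$counts > 0
  out <- tibble::tibble(distance = pr$centers[present],
                        gamma = g[present],
                        n_pairs = pr$counts[present])
  attr(out, "dropped_bins") <- sum(!present)
  class(out) <- c("variogram", class(out))
  out
}

# k-nearest-neighbour exponential smoothing operators for a geometry: one
# dense row-stochastic matrix per k in the bandwidth grid.
smoothing_kernels <- function(geometry, k_grid) {
  d <- geometry$distance
  np <- nrow(d)
  lapply(k_grid, function(k) {
    if (k == 0) return(NULL) # no-smoothing limit: plain permutation
    k <- min(k, np - 1L)
    w <- matrix(0, np, np)
    for (i in seq_len(np)) {
      nn <- order(d[i, ])[seq_len(k + 1L)] # includes self at distance 0
      dk <- d[i, nn[k + 1L]]
      w[i, nn] <- exp(-d[i, nn] / max(dk, .Machine$double.eps))
    }
    w / rowSums(w)
  })
}

default_k_grid <- function(n_parcels, n_bandwidths = 10) {
  k_max <- max(3L, floor(n_parcels / 4))
  unique(round(seq(3, k_max, length.out = n_bandwidths)))
}

#' Variogram-matched spatially autocorrelated surrogate maps
#'
#' Generates null maps that preserve the spatial autocorrelation (SA)
#' structure of a source map: each surrogate is built by (1) randomly
#' permuting the source values, (2) smoothing the permuted map with
#' distance-decaying exponential kernels over k nearest neighbours across a
#' bandwidth grid, (3) picking the bandwidth and affine rescaling
#' (`sqrt(a) * smoothed + sqrt(b) * noise`, a, b >= 0) that minimizes
#' squared error between the surrogate and source variograms, and (4)
#' optionally rank-remapping the result to the source value distribution
#' (default on), so each surrogate has exactly the source's value multiset.
#'
#' @param values per-parcel source map.
#' @param geometry a [parcel_geometry()].
#' @param n_surrogates number of surrogate maps.
#' @param seed integer seed; surrogates are deterministic given
#'   (map, geometry, n, seed).
#' @param k_grid bandwidth grid of neighbour counts; default 10 values from
#'   3 to `n_parcels / 4`. A grid of `{0}` yields plain permutations.
#' @param resample_values rank-remap surrogates to the source distribution.
#' @param n_bins,max_dist_quantile variogram binning (see
#'   [empirical_variogram()]).
#' @return object of class `surrogate_ensemble`: `maps`
#'   (n_surrogates x parcels), `match_score` (correlation between each
#'   surrogate's variogram and the source variogram), `seed`.
#' @export
generate_surrogates <- function(values, geometry, n_surrogates = 1000,
                                seed = NULL, k_grid = NULL,
                                resample_values = TRUE, n_bins = 25,
                                max_dist_quantile = 0.5) {
  stopifnot(inherits(geometry, "parcel_geometry"))
  n_surrogates <- assert_count(n_surrogates, "n_surrogates")
  np <- nrow(geometry$distance)
  if (length(values) != np) stop("Map length mismatch.", call. = FALSE)
  if (is.null(k_grid)) k_grid <- default_k_grid(np)
  if (any(k_grid > np - 1L)) {
    warning("Neighbour counts capped at n_parcels - 1.", call. = FALSE)
    k_grid <- unique(pmin(k_grid, np - 1L))
  }
  kernels <- smoothing_kernels(geometry, k_grid)
  pr <- variogram_pairs(geometry, n_bins, max_dist_quantile)
  present <- pr$counts > 0
  g_target <- gamma_vec(values, pr)[present]
  sorted_src <- sort(values)
  maps <- matrix(NA_real_, n_surrogates, np)
  score <- numeric(n_surrogates)
  with_seed(seed, {
    for (s in seq_len(n_surrogates)) {
      x0 <- values[sample.int(np)]
      noise <- stats::rnorm(np)
      best <- NULL; best_sse <- Inf
      for (kk in seq_along(kernels)) {
        sm <- if (is.null(kernels[[kk]])) x0 else
          as.numeric(kernels[[kk]] %*% x0)
        cand <- fit_affine_surrogate(sm, noise, g_target, pr, present)
        if (cand$sse < best_sse) { best_sse <- cand$sse; best <- cand$map }
      }
      if (resample_values) {
        best <- sorted_src[rank(best, ties.method = "first")]
      }
      maps[s, ] <- best
      g_s <- gamma_vec(best, pr)[present]
      score[s] <- if (stats::sd(g_s) == 0 || stats::sd(g_target) == 0) NA_real_
                  else stats::cor(g_s, g_target)
    }
  })
  structure(list(maps = maps, match_score = score, seed = seed,
                 source = values),
            class = "surrogate_ensemble")
}

# Least-squares fit of the target variogram as a + b over (smoothed, noise)
# variance components: gamma(sqrt(a) sm + sqrt(b) z) = a gamma_sm + b
# gamma_z. Coefficients clamped at zero.
fit_affine_surrogate <- function(sm, noise, g_target, pr, present) {
  g_sm <- gamma_vec(sm, pr)[present]
  g_z <- gamma_vec(noise, pr)[present]
  xm <- cbind(g_sm, g_z)
  coef <- tryCatch(stats::coef(stats::lm.fit(xm, g_target)),
                   error = function(e) c(1, 0))
  coef[!is.finite(coef)] <- 0
  coef <- pmax(coef, 0)
  if (sum(coef) == 0) coef <- c(1, 0)
  map <- sqrt(coef[1]) * sm + sqrt(coef[2]) * noise
  sse <- sum((g_target - xm %*% coef)^2)
  list(map = map, sse = sse)
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("Surrogate ensemble: %d maps x %d parcels; median variogram match %.3f\n",
              nrow(x$maps), ncol(x$maps),
              stats::median(x$match_score, na.rm = TRUE)))
  invisible(x)
}

#' Spin-style p-value for a map-to-map correlation
#'
#' Compares the observed correlation between two parcellated maps to the
#' distribution of correlations between SA-preserving surrogates of the
#' first map and the second map. Two-sided by default (compares |r|); the
#' attainable minimum is `1 / (n_surrogates + 1)`.
#'
#' @param map_a,map_b per-parcel maps; the ensemble must be built from
#'   `map_a`.
#' @param ensemble a [generate_surrogates()] result for `map_a`.
#' @param method correlation estimator, `"pearson"` or `"spearman"`.
#' @param alternative `"two.sided"` (default) or `"greater"` on signed r.
#' @return list with `r` (observed) and `p`.
#' @export
spin_pvalue <- function(map_a, map_b, ensemble,
                        method = c("pearson", "spearman"),
                        alternative = c("two.sided", "greater")) {
  method <- match.arg(method)
  alternative <- match.arg(alternative)
  stopifnot(inherits(ensemble, "surrogate_ensemble"))
  if (length(map_b) != ncol(ensemble$maps) ||
      length(map_a) != ncol(ensemble$maps)) {
    stop("Map length mismatch with ensemble.", call. = FALSE)
  }
  if (stats::sd(map_b) == 0) stop("`map_b` is constant.", call. = FALSE)
  cf <- if (method == "spearman") spearman_cor else stats::cor
  r_obs <- cf(map_a, map_b)
  r_null <- apply(ensemble$maps, 1, cf, y = map_b)
  n <- length(r_null)
  p <- if (alternative == "two.sided") {
    (1 + sum(abs(r_null) >= abs(r_obs) - 1e-12)) / (n + 1)
  } else {
    (1 + sum(r_null >= r_obs - 1e-12)) / (n + 1)
  }
  list(r = r_obs, p = p)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard FDR step-up control across a family of p-values.
#'
#' @param pvals p-values between 0 and 1.
#' @param alpha FDR level.
#' @return list with `significant` (logical mask, adjusted p <= alpha) and
#'   `p_adjusted`.
#' @export
bh_adjust <- function(pvals, alpha = 0.05) {
  if (length(pvals) == 0) stop("Empty p-value vector.", call. = FALSE)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  list(significant = adj <= alpha, p_adjusted = adj)
}
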