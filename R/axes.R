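#' Term axis: signed sets of meta-analytic terms aligned with a brain map
#'
#' Correlates every term-association z-map with a reference brain-loading
#' map (e.g. the Hurst-psychopathology pattern), assesses each correlation
#' against a single shared ensemble of SA-preserving surrogates of the
#' reference map, applies Benjamini-Hochberg correction across terms, and
#' splits the survivors by sign into a positive and a negative term set.
#'
#' @param hpp_map per-parcel reference map (e.g. LV-1 brain loadings).
#' @param terms a `term_map_set` (see [simulate_term_maps()]), or a
#'   terms x parcels matrix with rownames.
#' @param geometry a [parcel_geometry()].
#' @param n_surrogates surrogate count for the spin test.
#' @param alpha FDR level for the BH correction.
#' @param seed integer seed (surrogate generation).
#' @param method spatial correlation estimator.
#' @param ensemble optional precomputed [generate_surrogates()] ensemble of
#'   `hpp_map`, reused instead of generating a new one.
#' @return object of class `axis_result`: tibble with one row per term
#'   (`term`, `r`, `p_spin`, `p_adjusted`, `significant`, `set`), plus
#'   `positive_set` / `negative_set` attributes.
#' @export
term_axis <- function(hpp_map, terms, geometry, n_surrogates = 1000,
                      alpha = 0.01, seed = NULL,
                      method = c("pearson", "spearman"), ensemble = NULL) {
  method <- match.arg(method)
  z <- if (inherits(terms, "term_map_set")) terms$z_maps else as.matrix(terms)
  if (nrow(z) < 2L) stop("Need at least 2 term maps.", call. = FALSE)
  if (ncol(z) != length(hpp_map)) {
    stop("Term maps and reference map have different parcel counts.",
         call. = FALSE)
  }
  keep <- apply(z, 1, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant term map(s) skipped.", call. = FALSE)
  }
  if (is.null(ensemble)) {
    ensemble <- generate_surrogates(hpp_map, geometry,
                                    n_surrogates = n_surrogates, seed = seed)
  }
  labels <- rownames(z)
  if (is.null(labels)) labels <- sprintf("term_%03d", seq_len(nrow(z)))
  res <- purrr::map(which(keep), function(t) {
    spin_pvalue(hpp_map, z[t, ], ensemble, method = method)
  })
  out <- tibble::tibble(
    term = labels[keep],
    r = vapply(res, `[[`, numeric(1), "r"),
    p_spin = vapply(res, `[[`, numeric(1), "p")
  )
  bh <- bh_adjust(out$p_spin, alpha)
  out$p_adjusted <- bh$p_adjusted
  out$significant <- bh$significant
  out$set <- dplyr::case_when(out$significant & out$r > 0 ~ "positive",
                              out$significant & out$r < 0 ~ "negative",
                              TRUE ~ "none")
  attr(out, "positive_set") <- out$term[out$set == "positive"]
  attr(out, "negative_set") <- out$term[out$set == "negative"]
  class(out) <- c("axis_result", class(out))
  out
}

#' Combine term maps by elementwise maximum z
#'
#' Reduces a set of term z-maps to one map that is maximally representative
#' of the set: each parcel takes the maximum z across the selected maps
#' (a parcel with z-scores +2 and +3 in two maps gets +3).
#'
#' @param maps terms x parcels matrix (a subset of a `term_map_set`'s
#'   `z_maps`), or a single map as a vector.
#' @return per-parcel combined map.
#' @export
combine_term_maps <- function(maps) {
  if (is.null(maps) || length(maps) == 0) {
    stop("Empty term-map selection.", call. = FALSE)
  }
  if (is.vector(maps)) return(maps)
  if (nrow(maps) == 0) stop("Empty term-map selection.", call. = FALSE)
  apply(maps, 2, max)
}

roi_members <- function(map, z) which(map > z)

#' ROI difference sweep across z thresholds
#'
#' For every threshold z in the grid, parcels with combined positive-set z
#' above the threshold form the positive ROI (e.g. Task-Cognition) and
#' likewise for the negative ROI (Cue-Response). Per subject the statistic
#' is the mean of `per_subject_values` over the positive ROI minus the mean
#' over the negative ROI; this difference is correlated with `scores`
#' across subjects (Spearman by default), with a subject-permutation
#' p-value. Thresholds with an empty ROI are flagged and excluded from
#' inference rather than silently averaged over nothing.
#'
#' @param pos_map,neg_map per-parcel combined z maps.
#' @param per_subject_values subjects x parcels matrix (e.g. H maps).
#' @param scores per-subject scores (e.g. pattern scores).
#' @param z_grid thresholds; default 0.5 to 4 in steps of 0.05.
#' @param n_perm subject permutations per threshold.
#' @param seed integer seed.
#' @param method correlation estimator.
#' @return tibble with per-threshold `z`, ROI sizes, `delta`-score
#'   correlation `r`, permutation `p`, an `empty` flag (no parcels above
#'   threshold) and a `degenerate` flag (zero-variance difference).
#' @export
roi_sweep <- function(pos_map, neg_map, per_subject_values, scores,
                      z_grid = seq(0.5, 4, by = 0.05), n_perm = 1000,
                      seed = NULL, method = c("spearman", "pearson")) {
  method <- match.arg(method)
  v <- as_hurst_matrix(per_subject_values)
  if (length(scores) != nrow(v)) stop("Score length mismatch.", call. = FALSE)
  if (length(z_grid) == 0) stop("Empty threshold grid.", call. = FALSE)
  n <- nrow(v)
  rk_scores <- if (method == "spearman")
    rank(scores, ties.method = "average") else scores
  perm_idx <- with_seed(seed,
    replicate(n_perm, sample.int(n), simplify = TRUE))
  rows <- purrr::map(z_grid, function(z) {
    pos <- roi_members(pos_map, z)
    neg <- roi_members(neg_map, z)
    if (length(pos) == 0 || length(neg) == 0) {
      return(tibble::tibble(z = z, n_pos = length(pos), n_neg = length(neg),
                            r = NA_real_, p = NA_real_, empty = TRUE,
                            degenerate = FALSE))
    }
    delta <- rowMeans(v[, pos, drop = FALSE]) -
      rowMeans(v[, neg, drop = FALSE])
    if (stats::sd(delta) == 0 || stats::sd(scores) == 0) {
      return(tibble::tibble(z = z, n_pos = length(pos), n_neg = length(neg),
                            r = NA_real_, p = NA_real_, empty = FALSE,
                            degenerate = TRUE))
    }
    rk_delta <- if (method == "spearman")
      rank(delta, ties.method = "average") else delta
    r_obs <- stats::cor(rk_delta, rk_scores)
    r_perm <- apply(perm_idx, 2,
                    function(idx) stats::cor(rk_delta, rk_scores[idx]))
    p <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (n_perm + 1)
    tibble::tibble(z = z, n_pos = length(pos), n_neg = length(neg),
                   r = r_obs, p = p, empty = FALSE, degenerate = FALSE)
  })
  out <- dplyr::bind_rows(rows)
  if (all(out$empty)) {
    stop("Every threshold produced an empty ROI.", call. = FALSE)
  }
  class(out) <- c("roi_sweep", class(out))
  out
}

#' Block-level Hurst contrast analysis
#'
#' Contrasts block-level Hurst exponents between high and low working-memory
#' load (2-back minus 0-back) within term-defined ROIs across a z-threshold
#' sweep, and correlates the contrast with behavior (d-prime, accuracy) and
#' pattern scores. A negative contrast means H was suppressed under load.
#' Bootstrap standard deviations of each correlation come from resampling
#' subjects with replacement.
#'
#' @param h2back,h0back subjects x parcels block-level H matrices.
#' @param pos_map,neg_map combined z maps defining the cognitive and
#'   sensorimotor ROI families.
#' @param z_grid thresholds to sweep.
#' @param behavior tibble with `dprime` and `accuracy_2back` columns.
#' @param pattern_scores per-subject pattern scores (vector or
#'   [pattern_scores()] tibble).
#' @param n_boot bootstrap resamples per correlation.
#' @param seed integer seed.
#' @param method correlation estimator.
#' @return tibble with one row per (roi, threshold, outcome):
#'   `roi` ("cognitive"/"sensorimotor"), `z`, `n_parcels`, `outcome`, `r`,
#'   `boot_sd`, `empty`.
#' @export
block_contrast_analysis <- function(h2back, h0back, pos_map, neg_map,
                                    z_grid = seq(0.5, 4, by = 0.05),
                                    behavior, pattern_scores, n_boot = 1000,
                                    seed = NULL,
                                    method = c("spearman", "pearson")) {
  method <- match.arg(method)
  h2 <- as_hurst_matrix(h2back); h0 <- as_hurst_matrix(h0back)
  stopifnot(all(dim(h2) == dim(h0)))
  ps <- if (is.data.frame(pattern_scores)) pattern_scores$pattern_score
        else pattern_scores
  n <- nrow(h2)
  stopifnot(nrow(behavior) == n, length(ps) == n)
  outcomes <- list(dprime = behavior$dprime,
                   accuracy = behavior$accuracy_2back,
                   pattern_score = ps)
  cf <- function(a, b) if (method == "spearman") spearman_cor(a, b)
                       else stats::cor(a, b)
  boot_idx <- with_seed(seed,
    replicate(n_boot, sample.int(n, replace = TRUE), simplify = TRUE))
  contrast_mat <- h2 - h0
  rois <- list(cognitive = pos_map, sensorimotor = neg_map)
  rows <- purrr::map(names(rois), function(roi_name) {
    purrr::map(z_grid, function(z) {
      members <- roi_members(rois[[roi_name]], z)
      base <- tibble::tibble(roi = roi_name, z = z,
                             n_parcels = length(members))
      if (length(members) == 0) {
        return(dplyr::mutate(tidyr::crossing(base,
                                             outcome = names(outcomes)),
                             r = NA_real_, boot_sd = NA_real_, empty = TRUE))
      }
      contrast <- rowMeans(contrast_mat[, members, drop = FALSE])
      degenerate <- stats::sd(contrast) == 0
      purrr::map(names(outcomes), function(oc) {
        y <- outcomes[[oc]]
        if (degenerate || stats::sd(y) == 0) {
          return(dplyr::mutate(base, outcome = oc, r = NA_real_,
                               boot_sd = NA_real_, empty = TRUE))
        }
        r <- cf(contrast, y)
        r_boot <- apply(boot_idx, 2, function(idx) {
          cb <- contrast[idx]; yb <- y[idx]
          if (stats::sd(cb) == 0 || stats::sd(yb) == 0) return(NA_real_)
          cf(cb, yb)
        })
        dplyr::mutate(base, outcome = oc, r = r,
                      boot_sd = stats::sd(r_boot, na.rm = TRUE),
                      empty = FALSE)
      }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("block_contrast", class(out))
  out
}

#' Activation axis: per-region correlation of activation with pattern scores
#'
#' Correlates a task-contrast activation value (e.g. 2-back minus 0-back
#' betas) with per-subject pattern scores in every region, with
#' Benjamini-Hochberg correction across regions. A positive correlation
#' means more activation goes with stronger expression of the brain
#' pattern.
#'
#' @param pattern_scores per-subject scores (vector or [pattern_scores()]
#'   tibble).
#' @param activations subjects x regions matrix of contrast values.
#' @param alpha FDR level.
#' @param method correlation estimator.
#' @return tibble with `region`, `r`, `p`, `p_adjusted`, `significant`;
#'   constant regions are skipped.
#' @export
activation_axis <- function(pattern_scores, activations, alpha = 0.05,
                            method = c("spearman", "pearson")) {
  method <- match.arg(method)
  ps <- if (is.data.frame(pattern_scores)) pattern_scores$pattern_score
        else pattern_scores
  a <- as.matrix(activations)
  stopifnot(length(ps) == nrow(a))
  keep <- apply(a, 2, stats::sd) > 0
  if (!all(keep)) {
    warning(sum(!keep), " constant region(s) skipped.", call. = FALSE)
  }
  region_names <- colnames(a)
  if (is.null(region_names)) region_names <- paste0("region_", seq_len(ncol(a)))
  tests <- purrr::map(which(keep), function(j) {
    suppressWarnings(stats::cor.test(ps, a[, j], method = method,
                                     exact = FALSE))
  })
  out <- tibble::tibble(
    region = region_names[keep],
    r = vapply(tests, function(t) unname(t$estimate), numeric(1)),
    p = vapply(tests, `[[`, numeric(1), "p.value")
  )
  bh <- bh_adjust(out$p, alpha)
  out$p_adjusted <- bh$p_adjusted
  out$significant <- bh$significant
  out
}
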