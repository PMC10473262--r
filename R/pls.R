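#' Survey-weighted moments
#'
#' Population-style weighted mean, variance and covariance:
#' \eqn{\mu_W = \sum w_i x_i / \sum w_i},
#' \eqn{\sigma^2_W = \sum w_i (x_i - \mu_W)^2 / \sum w_i},
#' \eqn{cov_W = \sum w_i (x_i - \mu_{W,x})(y_i - \mu_{W,y}) / \sum w_i}.
#' With equal weights these reduce exactly to the arithmetic mean and the
#' 1/n (population) variance and covariance.
#'
#' @param x,y numeric vectors (`y` optional).
#' @param w positive weights, same length as `x`.
#' @return a list with `mean_x`, `var_x` and, when `y` is given, `mean_y`,
#'   `var_y`, `cov_xy`.
#' @export
weighted_moments <- function(x, y = NULL, w) {
  if (length(w) != length(x) || (!is.null(y) && length(y) != length(x))) {
    stop("`x`, `y` and `w` must have equal lengths.", call. = FALSE)
  }
  if (any(!is.finite(w)) || any(w <= 0)) {
    stop("Weights must be finite and strictly positive.", call. = FALSE)
  }
  sw <- sum(w)
  mx <- sum(w * x) / sw
  out <- list(mean_x = mx, var_x = sum(w * (x - mx)^2) / sw)
  if (!is.null(y)) {
    my <- sum(w * y) / sw
    out$mean_y <- my
    out$var_y <- sum(w * (y - my)^2) / sw
    out$cov_xy <- sum(w * (x - mx) * (y - my)) / sw
  }
  out
}

#' Survey-weighted (rank) correlation
#'
#' Corrected correlation \eqn{r = cov_W(x, y) / \sqrt{\sigma^2_W(x)
#' \sigma^2_W(y)}}. With `rank_transform = TRUE` both variables are first
#' converted to mid-ranks, giving a weighted Spearman analogue
#' (rank-then-weight order).
#'
#' @inheritParams weighted_moments
#' @param rank_transform convert `x` and `y` to mid-ranks first.
#' @return a single correlation between -1 and 1.
#' @export
weighted_correlation <- function(x, y, w = rep(1, length(x)),
                                 rank_transform = FALSE) {
  if (rank_transform) {
    x <- rank(x, ties.method = "average")
    y <- rank(y, ties.method = "average")
  }
  m <- weighted_moments(x, y, w)
  if (m$var_x <= 0 || m$var_y <= 0) {
    stop("Zero weighted variance: correlation undefined.", call. = FALSE)
  }
  m$cov_xy / sqrt(m$var_x * m$var_y)
}

# Weighted column means / population sds of a matrix.
wcolmeans <- function(m, w) colSums(m * w) / sum(w)
wcolsds <- function(m, w, mu) sqrt(colSums(w * sweep(m, 2, mu)^2) / sum(w))

# Cross-block covariance between centered X (n x p) and Y (n x q) with
# weights applied to the X-side deviations; sum(w) normalization.
cross_covariance <- function(xc, yc, w) {
  crossprod(xc * w, yc) / sum(w)
}

#' Behavioral PLS of a brain-by-outcome cross-block covariance
#'
#' Columns of both blocks are mean-centered (weighted means when sampling
#' weights are supplied) and the cross-block covariance matrix `X'Y` —
#' computed elementwise with the survey-weighted covariance when weighted —
#' is decomposed by singular value decomposition, `X'Y = U S V'`. Each
#' latent variable (LV) pairs a brain-loading column of `U` with a design
#' loading column of `V`; the fraction of cross-block covariance explained
#' by LV i is its squared singular value over the sum of squared singular
#' values. Loadings are covariance-scale by default; `scale_columns = TRUE`
#' z-scores the columns first (correlation-PLS variant).
#'
#' Sign convention: each LV is flipped so that its largest-magnitude design
#' loading is positive.
#'
#' @param x subjects x parcels matrix (or a `hurst_map`).
#' @param y subjects x outcomes matrix or factor-score tibble.
#' @param weights optional per-subject positive weights (vector or a
#'   `weights` tibble with a `weight` column).
#' @param scale_columns z-score columns before the decomposition.
#' @return object of class `pls_model` with `brain_loadings`,
#'   `design_loadings`, `singular_values`, `covariance_explained`, centering
#'   parameters, and bookkeeping fields later filled by
#'   [pls_permutation()] / [pls_bootstrap()].
#' @seealso [pls_analysis()] for the one-call fit + inference wrapper.
#' @export
fit_pls <- function(x, y, weights = NULL, scale_columns = FALSE) {
  x <- as_hurst_matrix(x)
  y <- as_factor_matrix(y)
  if (nrow(x) != nrow(y)) stop("Subject counts differ between blocks.",
                               call. = FALSE)
  if (anyNA(x) || anyNA(y)) {
    stop("Missing values are not allowed in PLS inputs.", call. = FALSE)
  }
  if (nrow(x) < ncol(y) + 1L) {
    stop("Need at least ", ncol(y) + 1L, " subjects.", call. = FALSE)
  }
  w <- resolve_weights(weights, nrow(x))
  mu_x <- wcolmeans(x, w); mu_y <- wcolmeans(y, w)
  xc <- sweep(x, 2, mu_x); yc <- sweep(y, 2, mu_y)
  sd_x <- sd_y <- NULL
  if (scale_columns) {
    sd_x <- wcolsds(x, w, mu_x); sd_y <- wcolsds(y, w, mu_y)
    if (any(sd_x <= 0) || any(sd_y <= 0)) {
      stop("Zero-variance column; cannot z-score.", call. = FALSE)
    }
    xc <- sweep(xc, 2, sd_x, "/"); yc <- sweep(yc, 2, sd_y, "/")
  }
  cc <- cross_covariance(xc, yc, w)
  sv <- svd(cc)
  tol <- max(dim(cc)) * max(sv$d) * .Machine$double.eps
  n_lv <- sum(sv$d > tol)
  if (n_lv < length(sv$d)) {
    message("Rank-deficient cross-block covariance: returning ", n_lv,
            " latent variable(s).")
  }
  u <- sv$u[, seq_len(n_lv), drop = FALSE]
  v <- sv$v[, seq_len(n_lv), drop = FALSE]
  d <- sv$d[seq_len(n_lv)]
  for (l in seq_len(n_lv)) {
    if (v[which.max(abs(v[, l])), l] < 0) {
      v[, l] <- -v[, l]; u[, l] <- -u[, l]
    }
  }
  rownames(v) <- colnames(y)
  structure(
    list(brain_loadings = u, design_loadings = v, singular_values = d,
         covariance_explained = d^2 / sum(d^2),
         cross_covariance = cc,
         weights = if (is.null(weights)) NULL else w,
         scale_columns = scale_columns,
         x_means = mu_x, y_means = mu_y, x_sds = sd_x, y_sds = sd_y,
         n_subjects = nrow(x), n_parcels = ncol(x),
         factor_names = colnames(y),
         perm_p = NULL, n_perm = NULL,
         brain_bootstrap_ratios = NULL, design_bootstrap_ratios = NULL,
         n_boot = NULL, seed = NULL),
    class = "pls_model"
  )
}

resolve_weights <- function(weights, n) {
  if (is.null(weights)) return(rep(1, n))
  if (is.data.frame(weights)) weights <- weights$weight
  if (length(weights) != n) stop("Weight length mismatch.", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    stop("Weights must be finite and strictly positive.", call. = FALSE)
  }
  as.numeric(weights)
}

#' Permutation test for PLS latent variables
#'
#' Rows of the brain block (and, in the weighted analysis, their weights)
#' are permuted while the outcome block is held fixed; the cross-block
#' covariance is recomputed — with the permuted weights applied to the
#' brain-side deviations and the unpermuted weight total in the denominator
#' — and decomposed. The p-value of LV i compares its observed singular
#' value with the rank-i permuted singular values:
#' `p = (1 + #{s_perm >= s_obs}) / (n_perm + 1)`.
#'
#' @inheritParams fit_pls
#' @param n_perm number of permutations (>= 100; fewer warns).
#' @param seed integer seed for the permutation stream.
#' @return numeric vector of per-LV p-values.
#' @export
pls_permutation <- function(x, y, weights = NULL, n_perm = 1000, seed = NULL,
                            scale_columns = FALSE) {
  x <- as_hurst_matrix(x); y <- as_factor_matrix(y)
  if (n_perm < 100) warning("Fewer than 100 permutations gives a coarse p.",
                            call. = FALSE)
  model <- fit_pls(x, y, weights, scale_columns)
  w <- resolve_weights(weights, nrow(x))
  n_lv <- length(model$singular_values)
  mu_y <- wcolmeans(y, w)
  yc <- sweep(y, 2, mu_y)
  if (model$scale_columns) yc <- sweep(yc, 2, model$y_sds, "/")
  n <- nrow(x)
  exceed <- numeric(n_lv)
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n)
      xp <- x[idx, , drop = FALSE]
      wp <- w[idx]
      mu_xp <- wcolmeans(xp, wp)
      xpc <- sweep(xp, 2, mu_xp)
      if (model$scale_columns) {
        xpc <- sweep(xpc, 2, wcolsds(xp, wp, mu_xp), "/")
      }
      d_perm <- svd(crossprod(xpc * wp, yc) / sum(w), nu = 0, nv = 0)$d
      exceed <- exceed +
        (d_perm[seq_len(n_lv)] >= model$singular_values - 1e-12)
    }
  })
  (1 + exceed) / (n_perm + 1)
}

#' Bootstrap ratios for PLS loadings
#'
#' Subjects are resampled with replacement jointly in both blocks (weights
#' travel with their subjects), the model is refit on each resample, and the
#' resampled LVs are matched to the original ones by maximal absolute dot
#' product of brain loadings (with sign alignment). The bootstrap ratio is
#' the original loading divided by the standard deviation of its bootstrap
#' distribution; under a null loading it behaves like a standard normal
#' deviate, so |BR| > 3 approximates p < 0.001.
#'
#' @inheritParams fit_pls
#' @param n_boot number of bootstrap resamples (>= 100; fewer warns).
#' @param seed integer seed.
#' @param max_redraws how many times a degenerate resample (zero-variance
#'   column) may be redrawn before erroring.
#' @return list with `brain` (parcels x LV) and `design` (outcomes x LV)
#'   bootstrap-ratio matrices and `n_redrawn`.
#' @export
pls_bootstrap <- function(x, y, weights = NULL, n_boot = 1000, seed = NULL,
                          scale_columns = FALSE, max_redraws = 100) {
  x <- as_hurst_matrix(x); y <- as_factor_matrix(y)
  if (n_boot < 100) warning("Fewer than 100 bootstrap resamples is unstable.",
                            call. = FALSE)
  model <- fit_pls(x, y, weights, scale_columns)
  w <- resolve_weights(weights, nrow(x))
  n <- nrow(x)
  n_lv <- length(model$singular_values)
  u0 <- model$brain_loadings
  acc_u <- array(NA_real_, dim = c(dim(u0), n_boot))
  acc_v <- array(NA_real_, dim = c(dim(model$design_loadings), n_boot))
  n_redrawn <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      for (try in seq_len(max_redraws)) {
        idx <- sample.int(n, replace = TRUE)
        xb <- x[idx, , drop = FALSE]; yb <- y[idx, , drop = FALSE]
        ok <- all(matrixStats_colsd(xb) > 0) && all(matrixStats_colsd(yb) > 0)
        if (ok) break
        n_redrawn <- n_redrawn + 1L
        if (try == max_redraws) stop("Too many degenerate resamples.",
                                     call. = FALSE)
      }
      mb <- fit_pls(xb, yb, w[idx], scale_columns)
      al <- align_loadings(u0, mb$brain_loadings)
      acc_u[, seq_along(al$order), b] <-
        sweep(mb$brain_loadings[, al$order, drop = FALSE], 2, al$signs, "*")
      acc_v[, seq_along(al$order), b] <-
        sweep(mb$design_loadings[, al$order, drop = FALSE], 2, al$signs, "*")
    }
  })
  sd_u <- apply(acc_u, c(1, 2), stats::sd, na.rm = TRUE)
  sd_v <- apply(acc_v, c(1, 2), stats::sd, na.rm = TRUE)
  brain <- u0 / sd_u
  design <- model$design_loadings / sd_v
  rownames(design) <- model$factor_names
  if (n_redrawn > 0) {
    message(n_redrawn, " degenerate bootstrap resample(s) redrawn.")
  }
  list(brain = brain, design = design, n_redrawn = n_redrawn)
}

matrixStats_colsd <- function(m) {
  mu <- colMeans(m)
  sqrt(colMeans(sweep(m, 2, mu)^2))
}

# Greedy LV matching: for each original LV pick the unused resampled LV with
# maximal |dot product| of brain loadings; sign from the dot product.
align_loadings <- function(u_ref, u_new) {
  k_ref <- ncol(u_ref); k_new <- ncol(u_new)
  dots <- crossprod(u_ref, u_new)  # k_ref x k_new
  order_out <- integer(min(k_ref, k_new))
  signs <- numeric(length(order_out))
  used <- rep(FALSE, k_new)
  for (l in seq_along(order_out)) {
    cand <- abs(dots[l, ])
    cand[used] <- -Inf
    m <- which.max(cand)
    order_out[l] <- m
    signs[l] <- ifelse(dots[l, m] >= 0, 1, -1)
    used[m] <- TRUE
  }
  list(order = order_out, signs = signs)
}

#' Fit a behavioral PLS model with permutation and bootstrap inference
#'
#' One-call wrapper: [fit_pls()] + [pls_permutation()] + [pls_bootstrap()],
#' with results stored on the returned `pls_model`.
#'
#' @inheritParams fit_pls
#' @param n_perm,n_boot permutation / bootstrap counts.
#' @param seed integer seed controlling both resampling streams.
#' @return a `pls_model` with `perm_p`, `brain_bootstrap_ratios` and
#'   `design_bootstrap_ratios` filled in.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(cohort_config(120, n_parcels = 24, seed = 2),
#'                        generate_timeseries = FALSE)
#' m <- pls_analysis(coh$truth$true_h, coh$factors,
#'                   n_perm = 200, n_boot = 200, seed = 3)
#' m$perm_p
#' }
#' @export
pls_analysis <- function(x, y, weights = NULL, n_perm = 1000, n_boot = 1000,
                         seed = NULL, scale_columns = FALSE) {
  model <- fit_pls(x, y, weights, scale_columns)
  model$perm_p <- pls_permutation(x, y, weights, n_perm = n_perm,
                                  seed = seed, scale_columns = scale_columns)
  br <- pls_bootstrap(x, y, weights, n_boot = n_boot,
                      seed = if (is.null(seed)) NULL else seed + 1L,
                      scale_columns = scale_columns)
  model$brain_bootstrap_ratios <- br$brain
  model$design_bootstrap_ratios <- br$design
  model$n_perm <- n_perm
  model$n_boot <- n_boot
  model$seed <- seed
  model
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("Behavioral PLS: %d subjects, %d parcels, %d outcome(s), %d LV(s)%s\n",
              x$n_subjects, x$n_parcels, nrow(x$design_loadings),
              length(x$singular_values),
              if (is.null(x$weights)) "" else " [weighted]"))
  tab <- data.frame(lv = seq_along(x$singular_values),
                    singular_value = signif(x$singular_values, 4),
                    cov_explained = signif(x$covariance_explained, 3))
  if (!is.null(x$perm_p)) tab$perm_p <- signif(x$perm_p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}
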