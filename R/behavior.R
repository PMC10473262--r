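erfc_inv <- function(y) -stats::qnorm(y / 2) / sqrt(2)

#' Signal-detection sensitivity (d-prime)
#'
#' \eqn{d' = -2\,\mathrm{erfc}^{-1}(2\,hit) + 2\,\mathrm{erfc}^{-1}(2\,fa)},
#' which equals \eqn{\sqrt{2}\,[\Phi^{-1}(hit) - \Phi^{-1}(fa)]} — i.e.
#' \eqn{\sqrt 2} times the conventional z-difference d'. Set
#' `conventional = TRUE` to divide by \eqn{\sqrt 2}.
#'
#' Rates of exactly 0 or 1 make the statistic infinite; when `n_trials` is
#' supplied they are clamped to `1/(2n)` and `1 - 1/(2n)` (the usual
#' half-count correction), otherwise to `eps` and `1 - eps`.
#'
#' @param hit,fa hit and false-alarm rates between 0 and 1 (vectorized).
#' @param n_trials optional trial count used for edge correction.
#' @param eps fallback edge correction when `n_trials` is unknown.
#' @param conventional divide by sqrt(2) to obtain the textbook
#'   `z(hit) - z(fa)` scaling.
#' @return numeric vector of sensitivities.
#' @examples
#' dprime(0.8, 0.2) # ~2.38
#' @export
dprime <- function(hit, fa, n_trials = NULL, eps = 0.01,
                   conventional = FALSE) {
  if (any(hit < 0 | hit > 1 | fa < 0 | fa > 1, na.rm = TRUE)) {
    stop("Rates must lie in [0, 1].", call. = FALSE)
  }
  lo <- if (is.null(n_trials)) eps else 1 / (2 * n_trials)
  hit <- pmin(pmax(hit, lo), 1 - lo)
  fa <- pmin(pmax(fa, lo), 1 - lo)
  d <- -2 * erfc_inv(2 * hit) + 2 * erfc_inv(2 * fa)
  if (conventional) d <- d / sqrt(2)
  d
}

#' Nonparticipation weight model
#'
#' Wraps an externally fitted linear predictor \eqn{\eta = X\hat B} of
#' inclusion in the analysis sample. Inclusion probabilities are
#' \eqn{\hat p = e^{\eta} / (1 + e^{\eta})} and the nonparticipation weights
#' are their inverses.
#'
#' @param linear_predictor per-subject linear predictor from a binary
#'   response model (the fitter itself is pluggable and out of scope here).
#' @return object of class `weight_model` with `linear_predictor`,
#'   `inclusion_prob`, `weights`.
#' @export
weight_model <- function(linear_predictor) {
  stopifnot(is.numeric(linear_predictor), all(is.finite(linear_predictor)))
  p <- stats::plogis(linear_predictor)
  structure(list(linear_predictor = linear_predictor, inclusion_prob = p,
                 weights = 1 / p),
            class = "weight_model")
}

#' Assemble a combined sampling-weight vector
#'
#' Multiplies weight streams elementwise (e.g. poststratification weights
#' times one or more nonparticipation weights). Streams may be plain
#' positive vectors or [weight_model()] objects, which contribute their
#' inverse-probability weights.
#'
#' @param ... weight streams, optionally named (names become provenance
#'   labels); alternatively a single list of streams.
#' @return tibble with `subject`, `weight`, and a `provenance` attribute.
#' @export
assemble_weights <- function(...) {
  streams <- list(...)
  if (length(streams) == 1L && is.list(streams[[1]]) &&
      !inherits(streams[[1]], "weight_model") &&
      !is.data.frame(streams[[1]]) && !is.numeric(streams[[1]])) {
    streams <- streams[[1]]
  }
  if (length(streams) == 0) stop("No weight streams given.", call. = FALSE)
  labels <- names(streams)
  if (is.null(labels)) labels <- rep("", length(streams))
  vecs <- purrr::imap(streams, function(s, i) {
    lbl <- if (is.character(i) && nzchar(i)) i else paste0("stream_", i)
    v <- if (inherits(s, "weight_model")) s$weights
         else if (is.data.frame(s)) s$weight
         else as.numeric(s)
    if (any(!is.finite(v)) || any(v <= 0)) {
      stop("Weight stream '", lbl, "' has non-positive or non-finite entries.",
           call. = FALSE)
    }
    stats::setNames(list(v), lbl)[[1]]
  })
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1L) {
    stop("Weight streams differ in length.", call. = FALSE)
  }
  w <- Reduce(`*`, vecs)
  out <- tibble::tibble(subject = seq_along(w), weight = w)
  attr(out, "provenance") <- names(vecs)
  out
}

#' Fisher-z confidence interval for a correlation
#'
#' \eqn{Z_r = \tfrac12\log\frac{1+r}{1-r}}, threshold
#' \eqn{Z_t = \Phi^{-1}(1-\alpha/2)\sqrt{1/(n-3)}}, and bounds
#' \eqn{\tanh(Z_r \mp Z_t)} — algebraically identical to the exponential
#' form \eqn{(e^{2(Z_r \mp Z_t)} - 1) / (e^{2(Z_r \mp Z_t)} + 1)}.
#'
#' @param r correlation(s) strictly inside (-1, 1).
#' @param n sample size(s) (> 3).
#' @param alpha two-sided significance level.
#' @return tibble with `low`, `high` (one row per r).
#' @examples
#' fisher_ci(0.5, 28) # ~ (0.156, 0.736)
#' @export
fisher_ci <- function(r, n, alpha = 0.05) {
  if (any(abs(r) >= 1)) stop("|r| must be < 1.", call. = FALSE)
  if (any(n <= 3)) stop("Need n > 3.", call. = FALSE)
  zr <- atanh(r)
  zt <- stats::qnorm(1 - alpha / 2) * sqrt(1 / (n - 3))
  tibble::tibble(low = tanh(zr - zt), high = tanh(zr + zt))
}

#' Stratified fold assignment
#'
#' Continuous covariates are quantile-binned (4 bins) and crossed with
#' categorical covariates to form strata; within each stratum subjects are
#' shuffled and dealt round-robin into folds (with a running offset so fold
#' sizes balance globally). Folds are disjoint and exhaustive.
#'
#' @param covariates data frame of per-subject stratification covariates
#'   (numeric columns are binned; character/factor/logical used as is).
#' @param k number of folds, `2 <= k <= n`.
#' @param seed integer seed.
#' @param n_bins quantile bins for continuous covariates.
#' @return integer vector of fold labels in 1..k.
#' @export
stratified_folds <- function(covariates, k, seed = NULL, n_bins = 4) {
  covariates <- as.data.frame(covariates)
  n <- nrow(covariates)
  k <- assert_count(k, "k", 2L)
  if (k > n) stop("`k` exceeds the number of subjects.", call. = FALSE)
  binned <- lapply(covariates, function(col) {
    if (is.numeric(col) && length(unique(col)) > n_bins) {
      br <- unique(stats::quantile(col, probs = seq(0, 1,
                                                    length.out = n_bins + 1)))
      cut(col, breaks = br, include.lowest = TRUE, labels = FALSE)
    } else {
      as.character(col)
    }
  })
  strata <- do.call(paste, c(binned, sep = "|"))
  folds <- integer(n)
  with_seed(seed, {
    offset <- 0L
    for (s in unique(strata)) {
      members <- which(strata == s)
      members <- members[sample.int(length(members))]
      folds[members] <- ((offset + seq_along(members) - 1L) %% k) + 1L
      offset <- (offset + length(members)) %% k
    }
  })
  folds
}

#' Stratified k-fold cross-validated PLS
#'
#' For each fold the PLS model is refit on the retained subjects and
#' compared with the full-data model: the fold's LV brain loadings are
#' correlated with the full-data loadings (sign-aligned) and benchmarked
#' against SA-preserving surrogates of the full-data map. Out-of-sample
#' brain scores are the dot products between the fold's brain loadings and
#' the left-out subjects' H maps, centered with the training fold's means
#' only (no leakage); these are correlated with left-out behavior and
#' factor scores, each with a Fisher confidence interval at the left-out
#' sample size.
#'
#' @param hurst subjects x parcels H matrix or `hurst_map`.
#' @param factors factor-score tibble/matrix; `factor_col` names the column
#'   correlated with the out-of-sample brain scores.
#' @param behavior behavior tibble; `behavior_col` names the outcome.
#' @param folds fold labels from [stratified_folds()].
#' @param geometry a [parcel_geometry()] for the spin benchmark.
#' @param full_model optional prefit full-data `pls_model`.
#' @param lv latent variable index compared across folds.
#' @param n_surrogates surrogates for the spin benchmark.
#' @param seed integer seed.
#' @param weights optional sampling weights used in all fits.
#' @param behavior_col,factor_col outcome column names.
#' @param method correlation estimator for score-outcome associations.
#' @return object of class `cv_result`: tibble with one row per fold
#'   (`fold`, `n_train`, `n_test`, `loading_cor`, `spin_p`, `r_behavior`
#'   with CI, `r_factor` with CI); skipped folds are dropped with a
#'   warning.
#' @export
crossval_pls <- function(hurst, factors, behavior, folds, geometry,
                         full_model = NULL, lv = 1, n_surrogates = 200,
                         seed = NULL, weights = NULL,
                         behavior_col = "accuracy_2back",
                         factor_col = "general",
                         method = c("spearman", "pearson")) {
  method <- match.arg(method)
  x <- as_hurst_matrix(hurst)
  y <- as_factor_matrix(factors)
  n <- nrow(x)
  stopifnot(length(folds) == n, nrow(behavior) == n)
  w <- resolve_weights(weights, n)
  if (is.null(full_model)) full_model <- fit_pls(x, y, weights)
  u_full <- full_model$brain_loadings[, lv]
  ensemble <- generate_surrogates(u_full, geometry,
                                  n_surrogates = n_surrogates, seed = seed)
  beh <- behavior[[behavior_col]]
  fac_idx <- match(factor_col, colnames(y))
  if (is.na(fac_idx)) stop("Unknown factor column '", factor_col, "'.",
                           call. = FALSE)
  cf <- function(a, b) if (method == "spearman") spearman_cor(a, b)
                       else stats::cor(a, b)
  rows <- list()
  for (f in sort(unique(folds))) {
    test <- which(folds == f); train <- which(folds != f)
    if (length(train) < ncol(y) + 1L || length(test) <= 4L) {
      warning("Fold ", f, " skipped: too few subjects.", call. = FALSE)
      next
    }
    mf <- fit_pls(x[train, , drop = FALSE], y[train, , drop = FALSE],
                  w[train])
    if (ncol(mf$brain_loadings) < lv) {
      warning("Fold ", f, " skipped: LV ", lv, " not identified.",
              call. = FALSE)
      next
    }
    u_f <- mf$brain_loadings[, lv]
    if (sum(u_f * u_full) < 0) u_f <- -u_f
    lc <- stats::cor(u_f, u_full)
    sp <- spin_pvalue(u_full, u_f, ensemble)$p
    scores <- sweep(x[test, , drop = FALSE], 2, mf$x_means) %*% u_f
    scores <- as.numeric(scores)
    r_beh <- cf(scores, beh[test])
    r_fac <- cf(scores, y[test, fac_idx])
    ci_b <- fisher_ci(r_beh, length(test))
    ci_f <- fisher_ci(r_fac, length(test))
    rows[[length(rows) + 1L]] <- tibble::tibble(
      fold = f, n_train = length(train), n_test = length(test),
      loading_cor = lc, spin_p = sp,
      r_behavior = r_beh, behavior_low = ci_b$low, behavior_high = ci_b$high,
      r_factor = r_fac, factor_low = ci_f$low, factor_high = ci_f$high
    )
  }
  if (length(rows) == 0) stop("All folds were skipped.", call. = FALSE)
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cv_result", class(out))
  out
}
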