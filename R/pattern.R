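#' Stable-region mask from bootstrap ratios
#'
#' Flags parcels whose loading on the chosen latent variable is stable, i.e.
#' whose absolute bootstrap ratio exceeds `threshold` (default 3, roughly
#' p < 0.001 under the normal approximation). The mask carries the sign of
#' the loading; in the motivating analysis only negative-loading regions
#' survive.
#'
#' @param model a `pls_model` with bootstrap ratios (see [pls_analysis()]).
#' @param lv latent-variable index.
#' @param threshold absolute bootstrap-ratio cutoff.
#' @return tibble with one row per parcel: `parcel`, `loading`,
#'   `bootstrap_ratio`, `stable`, `sign` (0 when not stable).
#' @export
stable_region_mask <- function(model, lv = 1, threshold = 3) {
  stopifnot(inherits(model, "pls_model"))
  if (is.null(model$brain_bootstrap_ratios)) {
    stop("Model has no bootstrap ratios; run pls_analysis()/pls_bootstrap().",
         call. = FALSE)
  }
  if (lv < 1 || lv > ncol(model$brain_bootstrap_ratios)) {
    stop("`lv` out of range.", call. = FALSE)
  }
  br <- model$brain_bootstrap_ratios[, lv]
  loading <- model$brain_loadings[, lv]
  stable <- abs(br) > threshold
  tibble::tibble(parcel = seq_along(br), loading = loading,
                 bootstrap_ratio = br, stable = stable,
                 sign = ifelse(stable, sign(loading), 0))
}

#' Per-subject pattern scores against a PLS brain-loading map
#'
#' The pattern score of a subject is the spatial correlation, across
#' parcels, between their Hurst map and the latent variable's brain
#' loadings: it measures how strongly the subject expresses the
#' Hurst-psychopathology pattern. `mean_stable_h` additionally averages the
#' subject's H over the stable-region mask (all stable parcels regardless of
#' loading sign).
#'
#' Because it is a correlation, the score is invariant to any affine
#' rescaling of the subject's map, so cohorts estimated under different
#' scanners or estimators can be scored against a common model.
#'
#' @param hurst a `hurst_map` or subjects x parcels matrix.
#' @param model a `pls_model` fit on a cohort with matching parcels.
#' @param lv latent-variable index.
#' @param threshold bootstrap-ratio cutoff for the stable mask.
#' @param method `"pearson"` (default) or `"spearman"` spatial correlation.
#' @return tibble with `subject`, `pattern_score`, `mean_stable_h`.
#' @export
pattern_scores <- function(hurst, model, lv = 1, threshold = 3,
                           method = c("pearson", "spearman")) {
  method <- match.arg(method)
  h <- as_hurst_matrix(hurst)
  stopifnot(inherits(model, "pls_model"))
  if (ncol(h) != model$n_parcels) {
    stop("Parcel count mismatch between map and model.", call. = FALSE)
  }
  loadings <- model$brain_loadings[, lv]
  mask <- NULL
  if (!is.null(model$brain_bootstrap_ratios)) {
    mask <- stable_region_mask(model, lv, threshold)
    if (!any(mask$stable)) {
      stop("No stable parcels at |BR| > ", threshold,
           "; mean_stable_h is undefined.", call. = FALSE)
    }
  }
  scores <- unname(apply(h, 1, function(row) {
    if (stats::sd(row) == 0) return(NA_real_)
    if (method == "spearman") spearman_cor(row, loadings)
    else stats::cor(row, loadings)
  }))
  if (anyNA(scores)) {
    warning(sum(is.na(scores)), " constant subject map(s): score set to NA.",
            call. = FALSE)
  }
  out <- tibble::tibble(subject = seq_len(nrow(h)), pattern_score = scores)
  out$mean_stable_h <- if (is.null(mask)) NA_real_ else
    rowMeans(h[, mask$parcel[mask$stable], drop = FALSE])
  out
}
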