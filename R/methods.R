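# broom-style tidiers and ggplot2 visual summaries.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a behavioral PLS model
#'
#' One row per (block, term, latent variable) with the loading and, when
#' available, its bootstrap ratio.
#'
#' @param x a `pls_model`.
#' @param ... unused.
#' @return a tibble with columns `block` ("brain"/"design"), `term`, `lv`,
#'   `loading`, `bootstrap_ratio`.
#' @export
tidy.pls_model <- function(x, ...) {
  n_lv <- length(x$singular_values)
  brain_terms <- sprintf("parcel_%04d", seq_len(x$n_parcels))
  design_terms <- x$factor_names %||% paste0("outcome_", seq_len(nrow(x$design_loadings)))
  long <- function(block, terms, loadings, brs) {
    tidyr::pivot_longer(
      tibble::as_tibble(stats::setNames(as.data.frame(loadings),
                                        paste0("lv", seq_len(n_lv)))) |>
        dplyr::mutate(block = block, term = terms, .before = 1),
      cols = dplyr::starts_with("lv"), names_to = "lv",
      names_prefix = "lv", values_to = "loading") |>
      dplyr::mutate(lv = as.integer(.data$lv),
                    bootstrap_ratio = if (is.null(brs)) NA_real_
                                      else as.vector(t(brs)))
  }
  dplyr::bind_rows(
    long("brain", brain_terms, x$brain_loadings, x$brain_bootstrap_ratios),
    long("design", design_terms, x$design_loadings,
         x$design_bootstrap_ratios)
  )
}

#' Glance at a behavioral PLS model
#'
#' @param x a `pls_model`.
#' @param ... unused.
#' @return a one-row tibble: sample sizes, leading LV's covariance
#'   explained and permutation p, and the number of stable parcels at
#'   |BR| > 3.
#' @export
glance.pls_model <- function(x, ...) {
  tibble::tibble(
    n_subjects = x$n_subjects, n_parcels = x$n_parcels,
    n_lv = length(x$singular_values),
    weighted = !is.null(x$weights),
    lv1_cov_explained = x$covariance_explained[1],
    lv1_perm_p = if (is.null(x$perm_p)) NA_real_ else x$perm_p[1],
    n_stable_parcels = if (is.null(x$brain_bootstrap_ratios)) NA_integer_
                       else sum(abs(x$brain_bootstrap_ratios[, 1]) > 3)
  )
}

#' @export
tidy.dfa_fit <- function(x, ...) x$scales

#' @export
glance.dfa_fit <- function(x, ...) {
  tibble::tibble(h = x$h, r_squared = x$r_squared,
                 n_scales = nrow(x$scales),
                 min_window = min(x$scales$window),
                 max_window = max(x$scales$window))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Log-log fluctuation plot of a DFA fit
#'
#' @param object a `dfa_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.dfa_fit <- function(object, ...) {
  ggplot2::ggplot(object$scales,
                  ggplot2::aes(x = log(.data$window),
                               y = log(.data$fluctuation))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = "log window size (frames)", y = "log F(n)",
                  title = sprintf("DFA: H = %.3f, R² = %.3f",
                                  object$h, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Design-loading summary plot for a PLS model
#'
#' Bar plot of the design (outcome) loadings of one latent variable,
#' annotated with bootstrap ratios when available.
#'
#' @param object a `pls_model`.
#' @param lv latent variable to display.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pls_model <- function(object, lv = 1, ...) {
  df <- tibble::tibble(
    outcome = factor(object$factor_names,
                     levels = object$factor_names),
    loading = object$design_loadings[, lv],
    stable = if (is.null(object$design_bootstrap_ratios)) FALSE
             else abs(object$design_bootstrap_ratios[, lv]) > 3
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$outcome, y = .data$loading,
                                   fill = .data$stable)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey70",
                                          `TRUE` = "#2166ac"),
                               name = "|BR| > 3") +
    ggplot2::labs(x = NULL, y = sprintf("LV %d design loading", lv),
                  title = sprintf("LV %d: %.0f%% covariance explained%s",
                                  lv,
                                  100 * object$covariance_explained[lv],
                                  if (is.null(object$perm_p)) "" else
                                    sprintf(", p = %.3g",
                                            object$perm_p[lv]))) +
    ggplot2::theme_minimal()
}

#' Variogram plot
#'
#' @param object a `variogram` tibble from [empirical_variogram()].
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.variogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$distance,
                                       y = .data$gamma)) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_area(max_size = 3, guide = "none") +
    ggplot2::labs(x = "distance (mm)", y = expression(gamma(d))) +
    ggplot2::theme_minimal()
}

#' Threshold-sweep plot
#'
#' Correlation (with permutation p where present) across ROI-defining
#' z thresholds.
#'
#' @param object a `roi_sweep` or `block_contrast` tibble.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.roi_sweep <- function(object, ...) {
  df <- dplyr::filter(object, !.data$empty)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$r)) +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::labs(x = "z threshold", y = "correlation") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.roi_sweep
#' @export
autoplot.block_contrast <- function(object, ...) {
  df <- dplyr::filter(object, !.data$empty)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$r,
                                   colour = .data$outcome)) +
    ggplot2::geom_line() +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$r - .data$boot_sd,
                                      ymax = .data$r + .data$boot_sd,
                                      fill = .data$outcome),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::facet_wrap(~ .data$roi) +
    ggplot2::labs(x = "z threshold", y = "correlation") +
    ggplot2::theme_minimal()
}

`%||%` <- function(a, b) if (is.null(a)) b else a
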