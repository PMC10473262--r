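#' DFA configuration
#'
#' Bundles the tuning parameters of detrended fluctuation analysis. Window
#' sizes are chosen so that the implied frequencies stay inside the band
#' `[f_low, f_high]`: a window of `n` frames at repetition time `tr` probes
#' fluctuations around `1 / (n * tr)` Hz. The defaults exclude slow scanner
#' drifts below 0.01 Hz and high-frequency physiological confounds above
#' 0.1 Hz.
#'
#' @param tr repetition time, seconds (> 0).
#' @param f_low low-frequency cutoff in Hz; caps the largest window at
#'   `floor(1 / (f_low * tr))` frames.
#' @param f_high high-frequency cutoff in Hz; sets the smallest window to
#'   `ceiling(1 / (f_high * tr))` frames. Must satisfy
#'   `f_high <= 1 / (2 * tr)` (Nyquist).
#' @param detrend_order polynomial order removed within each window
#'   (1 = linear, the classic DFA-1).
#' @param min_windows_per_scale smallest number of windows a scale may have;
#'   also caps the largest window at `floor(n_time / min_windows_per_scale)`.
#' @param max_n_scales cap on the number of window counts sampled from the
#'   admissible range; when more are admissible, that many evenly spaced
#'   integers are used.
#' @param reverse_pass if `TRUE`, fluctuations are averaged with a second
#'   pass over the time-reversed profile (off by default; the forward
#'   partition alone matches the usual description).
#' @return an object of class `dfa_config`.
#' @export
dfa_config <- function(tr, f_low = 0.01, f_high = 0.1, detrend_order = 1L,
                       min_windows_per_scale = 4L, max_n_scales = 30L,
                       reverse_pass = FALSE) {
  assert_scalar_number(tr, "tr", 0, Inf, strict = TRUE)
  assert_scalar_number(f_low, "f_low", 0, Inf, strict = TRUE)
  assert_scalar_number(f_high, "f_high", 0, Inf, strict = TRUE)
  if (f_low >= f_high) {
    stop("`f_low` must be strictly below `f_high` (got ", f_low, " >= ",
         f_high, ").", call. = FALSE)
  }
  nyquist <- 1 / (2 * tr)
  if (f_high > nyquist + 1e-12) {
    stop("`f_high` = ", f_high, " Hz exceeds the Nyquist frequency ",
         format(nyquist), " Hz at tr = ", tr, " s.", call. = FALSE)
  }
  structure(
    list(tr = tr, f_low = f_low, f_high = f_high,
         detrend_order = assert_count(detrend_order, "detrend_order", 0L),
         min_windows_per_scale =
           assert_count(min_windows_per_scale, "min_windows_per_scale", 1L),
         max_n_scales = assert_count(max_n_scales, "max_n_scales", 3L),
         reverse_pass = isTRUE(reverse_pass)),
    class = "dfa_config"
  )
}

#' Enumerate DFA window scales under the frequency constraint
#'
#' Window counts `N` are sampled approximately uniformly over the admissible
#' integer range; for each `N` the window size is the largest `n` with
#' `n * N <= n_time`, i.e. `n = floor(n_time / N)`. Sizes are restricted to
#' `[ceiling(1 / (f_high * tr)), min(floor(1 / (f_low * tr)),
#' floor(n_time / min_windows_per_scale))]`. Duplicate window sizes keep the
#' largest `N`.
#'
#' @param n_time number of time points.
#' @param config a [dfa_config()].
#' @return a tibble with columns `window` (n, frames) and `n_windows` (N),
#'   sorted by increasing window size.
#' @export
enumerate_scales <- function(n_time, config) {
  stopifnot(inherits(config, "dfa_config"))
  n_time <- assert_count(n_time, "n_time", 4L)
  n_min <- ceiling(1 / (config$f_high * config$tr))
  n_max_band <- floor(1 / (config$f_low * config$tr))
  n_max_len <- floor(n_time / config$min_windows_per_scale)
  n_max <- min(n_max_band, n_max_len)
  if (n_min > n_max) {
    stop("No admissible DFA window sizes: the band [", config$f_low, ", ",
         config$f_high, "] Hz at tr = ", config$tr, " s requires windows in [",
         n_min, ", ", n_max, "] frames for n_time = ", n_time,
         " (min ", config$min_windows_per_scale, " windows per scale).",
         call. = FALSE)
  }
  n_cand <- seq_len(floor(n_time / n_min))
  win <- floor(n_time / n_cand)
  keep <- win >= n_min & win <= n_max
  n_adm <- n_cand[keep]
  if (length(n_adm) == 0L) {
    stop("No admissible window counts for n_time = ", n_time, ".",
         call. = FALSE)
  }
  if (length(n_adm) > config$max_n_scales) {
    n_adm <- unique(round(seq(min(n_adm), max(n_adm),
                              length.out = config$max_n_scales)))
  }
  tbl <- tibble::tibble(n_windows = n_adm,
                        window = floor(n_time / n_adm))
  tbl <- dplyr::arrange(tbl, .data$window, dplyr::desc(.data$n_windows))
  tbl <- dplyr::distinct(tbl, .data$window, .keep_all = TRUE)
  if (nrow(tbl) < 3L) {
    stop("Fewer than 3 distinct DFA scales are admissible for n_time = ",
         n_time, "; widen the frequency band or supply a longer series.",
         call. = FALSE)
  }
  tbl
}

# Precompute the per-window-size QR decompositions used for local polynomial
# detrending, so panels of identical-length series reuse them.
dfa_detrenders <- function(scales, detrend_order) {
  lapply(seq_len(nrow(scales)), function(i) {
    n <- scales$window[i]
    t <- seq_len(n) / n
    qr(outer(t, 0:detrend_order, `^`))
  })
}

# Fluctuation function over precomputed scales for one series.
dfa_fluctuations <- function(x, scales, qrs, reverse_pass = FALSE) {
  prof <- cumsum(x - mean(x))
  f_pass <- function(p) {
    vapply(seq_len(nrow(scales)), function(i) {
      n <- scales$window[i]
      nw <- scales$n_windows[i]
      m <- n * nw
      y <- matrix(p[seq_len(m)], nrow = n)
      res <- qr.resid(qrs[[i]], y)
      sqrt(mean(res^2))
    }, numeric(1))
  }
  f <- f_pass(prof)
  if (reverse_pass) {
    f <- sqrt((f^2 + f_pass(rev(prof))^2) / 2)
  }
  f
}

dfa_regress <- function(scales, fluct) {
  lx <- log(scales$window)
  ly <- log(fluct)
  slope <- stats::cov(lx, ly) / stats::var(lx)
  r2 <- stats::cor(lx, ly)^2
  list(h = slope, r_squared = r2)
}

#' Estimate the Hurst exponent of one series by DFA
#'
#' The series is mean-centered and integrated into a profile; for each scale
#' the first `n * N` frames are partitioned into `N` contiguous windows, a
#' polynomial of `detrend_order` is removed within each window, and the
#' root-mean-square residual `F(n)` is recorded. The Hurst estimate is the
#' ordinary least-squares slope of `log F(n)` on `log n`, and `r_squared` is
#' the coefficient of determination of that regression — a mono-fractality
#' diagnostic that is always reported, never used to silently reject a fit.
#'
#' @param series numeric vector; must not be constant.
#' @param config a [dfa_config()].
#' @param scales optional explicit window sizes (integer vector of `n`
#'   values, frames) overriding [enumerate_scales()]; window counts are then
#'   `floor(length(series) / n)`.
#' @return an object of class `dfa_fit` with elements `h`, `r_squared`, and
#'   a `scales` tibble (`window`, `n_windows`, `fluctuation`).
#' @examples
#' fit <- dfa_fit(simulate_fgn(0.7, 1024, seed = 1), dfa_config(tr = 0.8))
#' fit$h
#' @export
dfa_fit <- function(series, config, scales = NULL) {
  stopifnot(inherits(config, "dfa_config"))
  if (!is.numeric(series) || any(!is.finite(series))) {
    stop("`series` must be a finite numeric vector.", call. = FALSE)
  }
  if (stats::sd(series) == 0) {
    stop("`series` is constant: fluctuations are identically zero and no ",
         "Hurst exponent is defined.", call. = FALSE)
  }
  n_time <- length(series)
  tbl <- resolve_scales(n_time, config, scales)
  qrs <- dfa_detrenders(tbl, config$detrend_order)
  f <- dfa_fluctuations(series, tbl, qrs, config$reverse_pass)
  if (any(f <= 0)) {
    stop("Zero fluctuation at one or more scales (degenerate series).",
         call. = FALSE)
  }
  reg <- dfa_regress(tbl, f)
  structure(
    list(h = reg$h, r_squared = reg$r_squared,
         scales = dplyr::mutate(tbl, fluctuation = f),
         config = config),
    class = "dfa_fit"
  )
}

resolve_scales <- function(n_time, config, scales = NULL) {
  if (is.null(scales)) return(enumerate_scales(n_time, config))
  if (is.data.frame(scales)) {
    stopifnot(all(c("window", "n_windows") %in% names(scales)))
    return(tibble::as_tibble(scales))
  }
  win <- sort(unique(as.integer(scales)))
  win <- win[win >= 2 & win <= floor(n_time / 2)]
  if (length(win) < 3L) {
    stop("Need at least 3 admissible window sizes within the series length.",
         call. = FALSE)
  }
  tibble::tibble(window = win, n_windows = floor(n_time / win))
}

#' @export
print.dfa_fit <- function(x, ...) {
  cat(sprintf("DFA fit: H = %.4f (R^2 = %.4f, %d scales, windows %d-%d)\n",
              x$h, x$r_squared, nrow(x$scales), min(x$scales$window),
              max(x$scales$window)))
  invisible(x)
}

#' Hurst exponents for a subjects x parcels panel
#'
#' Applies [dfa_fit()] to every parcel time series of every subject. When the
#' panel carries multiple runs they are first averaged frame-wise per
#' subject. Parcels with constant series yield `NA` with a warning rather
#' than an error.
#'
#' @param panel a [ts_panel()] or a subjects x parcels x time array.
#' @param config a [dfa_config()]; if `NULL`, built from the panel's `tr`
#'   with default band limits.
#' @param scales optional explicit window sizes passed to [dfa_fit()].
#' @return an object of class `hurst_map`: list with `values` and
#'   `fit_quality` (subjects x parcels matrices) and `config`.
#' @export
hurst_panel <- function(panel, config = NULL, scales = NULL) {
  panel <- as_ts_panel(panel)
  if (is.null(config)) config <- dfa_config(tr = panel$tr)
  bold <- panel_mean_runs(panel)
  n_sub <- dim(bold)[1]; n_par <- dim(bold)[2]; n_time <- dim(bold)[3]
  tbl <- resolve_scales(n_time, config, scales)
  qrs <- dfa_detrenders(tbl, config$detrend_order)
  values <- matrix(NA_real_, n_sub, n_par)
  quality <- matrix(NA_real_, n_sub, n_par)
  n_constant <- 0L
  for (i in seq_len(n_sub)) {
    for (j in seq_len(n_par)) {
      x <- bold[i, j, ]
      if (stats::sd(x) == 0) {
        n_constant <- n_constant + 1L
        next
      }
      f <- dfa_fluctuations(x, tbl, qrs, config$reverse_pass)
      if (any(f <= 0)) {
        n_constant <- n_constant + 1L
        next
      }
      reg <- dfa_regress(tbl, f)
      values[i, j] <- reg$h
      quality[i, j] <- reg$r_squared
    }
  }
  if (n_constant > 0L) {
    warning(n_constant, " constant/degenerate parcel series set to NA.",
            call. = FALSE)
  }
  structure(list(values = values, fit_quality = quality, config = config,
                 scales = tbl),
            class = "hurst_map")
}

#' @export
print.hurst_map <- function(x, ...) {
  cat(sprintf("Hurst map: %d subjects x %d parcels; mean H = %.3f, mean R^2 = %.3f\n",
              nrow(x$values), ncol(x$values),
              mean(x$values, na.rm = TRUE),
              mean(x$fit_quality, na.rm = TRUE)))
  invisible(x)
}

#' Per-condition block-level Hurst exponents
#'
#' Estimates H separately within every task block of the requested
#' condition, then averages across same-condition blocks per subject and
#' parcel. Within a block the scale range is adapted: the smallest window is
#' unchanged while the largest is capped at
#' `floor(block_length / min_windows_per_scale)`. Blocks too short to admit
#' at least 3 scales are skipped with a warning; if every block is skipped
#' the cell is `NA`.
#'
#' @param panel a [ts_panel()].
#' @param design a block-design tibble with columns `condition`, `onset`
#'   (0-based frame index) and `duration` (frames); defaults to the design
#'   attached to the panel.
#' @param condition block label to analyze, e.g. `"2-back"`.
#' @param config a [dfa_config()]; for typical block lengths a wider
#'   high-frequency bound than the full-run default is needed (short windows
#'   only exist below ~0.1 Hz for long runs).
#' @return subjects x parcels matrix of block-averaged H.
#' @export
block_hurst <- function(panel, design = NULL, condition, config = NULL) {
  panel <- as_ts_panel(panel)
  if (is.null(design)) design <- panel$design
  if (is.null(design)) stop("No block design supplied.", call. = FALSE)
  if (is.null(config)) config <- dfa_config(tr = panel$tr)
  blocks <- design[design$condition == condition, , drop = FALSE]
  if (nrow(blocks) == 0L) {
    stop("No blocks with condition '", condition, "' in the design.",
         call. = FALSE)
  }
  bold <- panel_mean_runs(panel)
  n_time <- dim(bold)[3]
  usable <- list()
  for (b in seq_len(nrow(blocks))) {
    len <- blocks$duration[b]
    i0 <- blocks$onset[b] + 1L
    i1 <- blocks$onset[b] + len
    if (i1 > n_time) stop("Block ", b, " extends past the series.", call. = FALSE)
    sc <- try(block_scales(len, config), silent = TRUE)
    if (inherits(sc, "try-error")) {
      warning("Skipping a '", condition, "' block of ", len,
              " frames: too short for the configured scale range.",
              call. = FALSE)
      next
    }
    usable[[length(usable) + 1L]] <-
      list(idx = i0:i1, scales = sc,
           qrs = dfa_detrenders(sc, config$detrend_order))
  }
  n_sub <- dim(bold)[1]; n_par <- dim(bold)[2]
  out <- matrix(NA_real_, n_sub, n_par)
  if (length(usable) == 0L) {
    warning("All '", condition, "' blocks were skipped; returning NA.",
            call. = FALSE)
    return(out)
  }
  for (i in seq_len(n_sub)) {
    for (j in seq_len(n_par)) {
      hs <- vapply(usable, function(u) {
        x <- bold[i, j, u$idx]
        if (stats::sd(x) == 0) return(NA_real_)
        f <- dfa_fluctuations(x, u$scales, u$qrs, config$reverse_pass)
        if (any(f <= 0)) return(NA_real_)
        dfa_regress(u$scales, f)$h
      }, numeric(1))
      if (all(is.na(hs))) next
      out[i, j] <- mean(hs, na.rm = TRUE)
    }
  }
  out
}

# Scale table for a block of `len` frames: n_min from the band, n_max capped
# by the block length.
block_scales <- function(len, config) {
  n_min <- ceiling(1 / (config$f_high * config$tr))
  n_max <- min(floor(1 / (config$f_low * config$tr)),
               floor(len / config$min_windows_per_scale))
  if (n_min > n_max) stop("empty block scale range")
  n_cand <- seq_len(floor(len / n_min))
  win <- floor(len / n_cand)
  keep <- win >= n_min & win <= n_max
  if (!any(keep)) stop("empty block scale range")
  tbl <- tibble::tibble(n_windows = n_cand[keep], window = win[keep])
  tbl <- dplyr::arrange(tbl, .data$window, dplyr::desc(.data$n_windows))
  tbl <- dplyr::distinct(tbl, .data$window, .keep_all = TRUE)
  if (nrow(tbl) < 3L) stop("fewer than 3 block scales")
  tbl
}
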