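cfg08 <- dfa_config(tr = 0.8)

test_that("scale enumeration respects the frequency band", {
  # tr = 0.8 s, band [0.01, 0.1] Hz: windows in [ceil(12.5), min(125, 90)].
  sc <- enumerate_scales(362, cfg08)
  expect_true(all(sc$window >= 13 & sc$window <= 90))
  expect_true(all(sc$window * sc$n_windows <= 362))
  expect_false(any(duplicated(sc$window)))
  expect_gte(nrow(sc), 3)
  # Without the min-windows cap the band alone allows windows up to 125.
  sc1 <- enumerate_scales(362, dfa_config(tr = 0.8,
                                          min_windows_per_scale = 1))
  expect_lte(max(sc1$window), 125)
  expect_gt(max(sc1$window), 90) # the band cap, not the length cap, binds
  expect_error(dfa_config(tr = 0.8, f_low = 0.2, f_high = 0.1),
               "strictly below")
  expect_error(dfa_config(tr = 0.8, f_high = 1), "Nyquist")
  expect_error(enumerate_scales(20, cfg08), "admissible")
})

test_that("white noise estimates H near 0.5", {
  hs <- vapply(1:60, function(s) {
    dfa_fit(simulate_fgn(0.5, 362, seed = 1000 + s), cfg08)$h
  }, numeric(1))
  expect_lt(abs(mean(hs) - 0.5), 0.05)
})

test_that("fGn H is recovered and agrees with a periodogram oracle", {
  scales <- round(exp(seq(log(16), log(512), length.out = 20)))
  h_dfa <- h_psd <- numeric(40)
  for (s in 1:40) {
    x <- simulate_fgn(0.8, 4096, seed = s)
    h_dfa[s] <- dfa_fit(x, cfg08, scales = scales)$h
    # Independent oracle: H = (1 - spectral slope) / 2 for fGn.
    sp <- stats::spec.pgram(x, plot = FALSE, taper = 0)
    keep <- sp$freq > 0.005 & sp$freq < 0.25
    beta <- -coef(lm(log(sp$spec[keep]) ~ log(sp$freq[keep])))[2]
    h_psd[s] <- (1 + beta) / 2
  }
  expect_lt(abs(mean(h_dfa) - 0.8), 0.05)
  expect_lt(abs(mean(h_dfa) - mean(h_psd)), 0.05)
})

test_that("estimates are exactly invariant to scaling and shifting", {
  x <- simulate_fgn(0.7, 362, seed = 3)
  f0 <- dfa_fit(x, cfg08)
  expect_equal(dfa_fit(5.7 * x, cfg08)$h, f0$h)
  expect_equal(dfa_fit(x + 100, cfg08)$h, f0$h)
})

test_that("mean estimates increase monotonically in true h", {
  grid <- c(0.5, 0.6, 0.7, 0.8, 0.9)
  means <- vapply(grid, function(h) {
    mean(vapply(1:30, function(s) {
      dfa_fit(simulate_fgn(h, 1024, seed = 40 * h * 100 + s), cfg08)$h
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("degenerate inputs error or carry diagnostics", {
  expect_error(dfa_fit(rep(1, 362), cfg08), "constant")
  # A pure ramp is not scale-free; the fit must surface its R^2 rather than
  # pretend the estimate is a valid Hurst exponent.
  f <- dfa_fit(seq_len(362) * 0.01, cfg08)
  expect_true(is.finite(f$r_squared))
  expect_gt(f$h, 1) # far outside (0, 1): visibly not fGn-like
})

test_that("fit R^2 on fGn input is high in nearly all runs", {
  r2 <- vapply(1:60, function(s) {
    dfa_fit(simulate_fgn(0.7, 1024, seed = 300 + s), cfg08)$r_squared
  }, numeric(1))
  expect_gte(mean(r2 > 0.95), 0.95)
})

test_that("hurst_panel recovers planted H fields and handles runs", {
  coh <- small_ts_cohort()
  hm <- hurst_panel(coh$panel)
  expect_s3_class(hm, "hurst_map")
  expect_equal(dim(hm$values), dim(coh$truth$true_h))
  r <- cor(as.vector(hm$values), as.vector(coh$truth$true_h))
  expect_gt(r, 0.7)
  # Averaging two identical runs is the identity.
  bold <- coh$panel$runs[[1]][1:4, , , drop = FALSE]
  one <- hurst_panel(ts_panel(bold, tr = 0.8))
  two <- hurst_panel(ts_panel(list(bold, bold), tr = 0.8))
  expect_equal(one$values, two$values)
  # Constant parcel becomes NA with a warning, not an error.
  bold2 <- bold
  bold2[1, 1, ] <- 3
  expect_warning(hmc <- hurst_panel(ts_panel(bold2, tr = 0.8)), "constant")
  expect_true(is.na(hmc$values[1, 1]))
  expect_false(anyNA(hmc$values[-1, ]))
})

test_that("block-level estimation reduces to the full fit for one big block", {
  x <- simulate_fgn(0.7, 360, seed = 9)
  bold <- array(x, dim = c(1, 1, 360))
  design <- tibble::tibble(condition = "2-back", onset = 0L,
                           duration = 360L)
  panel <- ts_panel(bold, tr = 0.8, design = design)
  hb <- block_hurst(panel, condition = "2-back", config = cfg08)
  full <- dfa_fit(x, cfg08)
  expect_equal(hb[1, 1], full$h, tolerance = 1e-10)
})

test_that("same-condition blocks are averaged; short blocks are skipped", {
  x <- simulate_fgn(0.6, 320, seed = 10)
  bold <- array(x, dim = c(1, 1, 320))
  design <- tibble::tibble(condition = c("2-back", "2-back"),
                           onset = c(0L, 160L), duration = c(160L, 160L))
  panel <- ts_panel(bold, tr = 0.8, design = design)
  cfg_blk <- dfa_config(tr = 0.8, f_high = 0.3)
  hb <- block_hurst(panel, condition = "2-back", config = cfg_blk)
  h1 <- dfa_fit(x[1:160], cfg_blk,
                scales = hurstpls:::block_scales(160, cfg_blk))$h
  h2 <- dfa_fit(x[161:320], cfg_blk,
                scales = hurstpls:::block_scales(160, cfg_blk))$h
  expect_equal(hb[1, 1], mean(c(h1, h2)), tolerance = 1e-10)
  # Blocks shorter than the admissible range are skipped with a warning.
  design_short <- tibble::tibble(condition = "2-back", onset = 0L,
                                 duration = 12L)
  panel_s <- ts_panel(bold, tr = 0.8, design = design_short)
  w <- testthat::capture_warnings(
    hs <- block_hurst(panel_s, condition = "2-back", config = cfg_blk))
  expect_match(w, "skipped|Skipping", all = TRUE)
  expect_true(is.na(hs[1, 1]))
})

test_that("planted 2-back suppression is recovered in cognitive parcels", {
  coh <- small_ts_cohort()
  cfg_blk <- dfa_config(tr = 0.8, f_high = 0.3)
  h2 <- block_hurst(coh$panel, condition = "2-back", config = cfg_blk)
  h0 <- block_hurst(coh$panel, condition = "0-back", config = cfg_blk)
  cog <- coh$truth$cognitive_parcels
  contrast <- rowMeans(h2[, cog, drop = FALSE] - h0[, cog, drop = FALSE])
  hi <- coh$truth$ability > quantile(coh$truth$ability, 0.5)
  # More able subjects suppress H more under load.
  expect_lt(mean(contrast[hi]), mean(contrast[!hi]))
  expect_lt(cor(contrast, coh$truth$ability), 0)
})
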