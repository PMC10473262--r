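test_that("max-z combination dominates its inputs", {
  m <- rbind(c(2, -1, 0.5), c(3, -2, 0.1))
  expect_equal(combine_term_maps(m), c(3, -1, 0.5))
  expect_equal(combine_term_maps(m[1, , drop = TRUE]), m[1, ])
  comb <- combine_term_maps(m)
  expect_true(all(comb >= m[1, ] & comb >= m[2, ]))
  expect_error(combine_term_maps(m[0, , drop = FALSE]), "Empty")
})

test_that("term axis recovers planted signed terms and only those", {
  g <- test_geometry(120, seed = 41)
  set.seed(12)
  hpp <- as.numeric(hurstpls:::grf_maps(1, g, 30))
  tm <- simulate_term_maps(g, n_terms = 40, smoothness = 30,
                           planted_target = hpp, n_planted_pos = 3,
                           n_planted_neg = 2, mixing_weight = 0.85,
                           seed = 13)
  ax <- term_axis(hpp, tm, g, n_surrogates = 999, alpha = 0.01, seed = 14)
  expect_setequal(attr(ax, "positive_set"), tm$labels[1:3])
  expect_setequal(attr(ax, "negative_set"), tm$labels[4:5])
  expect_true(all(ax$r[ax$set == "positive"] > 0))
  expect_true(all(ax$r[ax$set == "negative"] < 0))
  # Affine rescaling of the reference map leaves the term sets unchanged.
  ax2 <- term_axis(2.5 * hpp + 3, tm, g, n_surrogates = 999, alpha = 0.01,
                   seed = 14)
  expect_equal(ax2$r, ax$r, tolerance = 1e-9)
  expect_equal(ax2$set, ax$set)
})

test_that("all-noise term sets rarely yield survivors", {
  g <- test_geometry(60, seed = 31)
  hits <- vapply(1:20, function(r) {
    set.seed(900 + r)
    hpp <- as.numeric(hurstpls:::grf_maps(1, g, 30))
    tm <- simulate_term_maps(g, n_terms = 25, smoothness = 30,
                             seed = 950 + r)
    ax <- term_axis(hpp, tm, g, n_surrogates = 199, alpha = 0.01,
                    seed = 990 + r)
    sum(ax$significant)
  }, numeric(1))
  expect_gte(mean(hits == 0), 0.9)
})

test_that("roi_sweep depends only on ROI membership and flags empties", {
  coh <- truth_cohort()
  np <- 40
  pos <- c(rep(3, 10), rep(0, 30))
  neg <- c(rep(0, 30), rep(3, 10))
  scores <- coh$truth$latent_scores
  sw <- roi_sweep(pos, neg, coh$truth$true_h, scores,
                  z_grid = c(1, 2, 2.9), n_perm = 200, seed = 3)
  # Same membership at all three thresholds -> identical correlations.
  expect_equal(sw$r, rep(sw$r[1], 3))
  expect_equal(sw$n_pos, rep(10L, 3))
  # Raising z values above threshold without changing membership is inert.
  sw2 <- roi_sweep(ifelse(pos > 0, 9, 0), ifelse(neg > 0, 9, 0),
                   coh$truth$true_h, scores, z_grid = c(1, 2, 2.9),
                   n_perm = 200, seed = 3)
  expect_equal(sw2$r, sw$r)
  # Thresholds above the map maximum are flagged, not silently averaged.
  sw3 <- roi_sweep(pos, neg, coh$truth$true_h, scores,
                   z_grid = c(2, 10), n_perm = 100, seed = 3)
  expect_true(sw3$empty[2])
  expect_true(is.na(sw3$r[2]))
  expect_error(roi_sweep(pos, neg, coh$truth$true_h, scores,
                         z_grid = 99), "empty ROI")
  # Identical values in both ROIs: delta degenerate -> flagged.
  const_vals <- matrix(1, 50, np) + matrix(rnorm(50), 50, np)
  swd <- roi_sweep(pos, neg, const_vals, scores[1:50], z_grid = 2,
                   n_perm = 100, seed = 4)
  expect_true(swd$degenerate[1])
  expect_true(is.na(swd$r[1]))
})

test_that("sweep signs follow the planted mechanisms", {
  coh <- truth_cohort()
  cog <- coh$truth$cognitive_parcels
  pos <- ifelse(seq_len(40) %in% cog, 3, 0)
  neg <- ifelse(seq_len(40) %in% cog, 0, 3)
  m <- truth_model()
  ps <- pattern_scores(coh$truth$true_h, m)
  # On the full-run truth only the severity channel operates: severity
  # lowers H more where loadings are larger (the cognitive set), so the
  # cognitive-minus-other difference falls with pattern scores.
  sw <- roi_sweep(pos, neg, coh$truth$true_h, ps$pattern_score,
                  z_grid = c(1, 2), n_perm = 300, seed = 6)
  expect_true(all(sw$r < 0))
  expect_true(all(sw$p < 0.05))
  # In the measured time series the load-dependent suppression channel
  # (able subjects suppress cognitive H under load; ability is negatively
  # coupled to severity) reverses the sign, matching the working-memory
  # engagement account: the relative H difference rises with pattern
  # scores. Verified end-to-end on the small time-series cohort.
  coh_ts <- small_ts_cohort()
  hm <- hurst_panel(coh_ts$panel)
  m_ts <- fit_pls(hm, coh_ts$factors)
  ps_ts <- pattern_scores(hm, m_ts)
  cog_ts <- coh_ts$truth$cognitive_parcels
  pos_ts <- ifelse(seq_len(24) %in% cog_ts, 3, 0)
  neg_ts <- ifelse(seq_len(24) %in% cog_ts, 0, 3)
  sw_ts <- roi_sweep(pos_ts, neg_ts, hm$values, ps_ts$pattern_score,
                     z_grid = 2, n_perm = 300, seed = 8)
  expect_gt(sw_ts$r[1], 0)
})

test_that("block contrasts recover suppression-performance coupling", {
  coh <- small_ts_cohort()
  cfg_blk <- dfa_config(tr = 0.8, f_high = 0.3)
  h2 <- block_hurst(coh$panel, condition = "2-back", config = cfg_blk)
  h0 <- block_hurst(coh$panel, condition = "0-back", config = cfg_blk)
  cog <- coh$truth$cognitive_parcels
  pos <- ifelse(seq_len(24) %in% cog, 3, 0)
  neg <- ifelse(seq_len(24) %in% cog, 0, 3)
  bc <- block_contrast_analysis(h2, h0, pos, neg, z_grid = c(1, 2),
                                behavior = coh$behavior,
                                pattern_scores = rep(0.1, 60) +
                                  scale(coh$truth$latent_scores)[, 1],
                                n_boot = 200, seed = 7)
  expect_tbl_names(bc, c("roi", "z", "outcome", "r", "boot_sd", "empty"))
  cogd <- dplyr::filter(bc, roi == "cognitive", outcome == "dprime")
  # More suppression (more negative contrast) with better performance.
  expect_true(all(cogd$r < 0))
  expect_true(all(cogd$boot_sd > 0))
  # Degenerate: identical blocks -> no contrast to correlate.
  bc0 <- block_contrast_analysis(h2, h2, pos, neg, z_grid = 1,
                                 behavior = coh$behavior,
                                 pattern_scores = coh$truth$latent_scores,
                                 n_boot = 100, seed = 8)
  expect_true(all(bc0$empty))
})

test_that("bootstrap SD shrinks roughly as 1/sqrt(n)", {
  set.seed(20)
  n_big <- 400
  contrast <- rnorm(n_big)
  outcome <- 0.4 * contrast + rnorm(n_big)
  h2 <- matrix(contrast, n_big, 2); h0 <- matrix(0, n_big, 2)
  beh <- tibble::tibble(dprime = outcome, accuracy_2back = outcome)
  sd_for <- function(idx) {
    bc <- block_contrast_analysis(h2[idx, ], h0[idx, ], c(3, 3), c(3, 3),
                                  z_grid = 1, behavior = beh[idx, ],
                                  pattern_scores = outcome[idx],
                                  n_boot = 400, seed = 9)
    dplyr::filter(bc, roi == "cognitive", outcome == "dprime")$boot_sd
  }
  ratio <- sd_for(1:100) / sd_for(1:400)
  expect_lt(abs(ratio - 2), 1)
})

test_that("activation axis flags planted couplings and respects the null", {
  coh <- truth_cohort()
  m <- truth_model()
  ps <- pattern_scores(coh$truth$true_h, m)
  n <- nrow(coh$factors)
  set.seed(33)
  act <- matrix(rnorm(n * 30), n, 30)
  # Region 1 equals the scores; regions 2-4 planted negative coupling.
  act[, 1] <- ps$pattern_score
  for (j in 2:4) {
    act[, j] <- -ps$pattern_score + rnorm(n, sd = sd(ps$pattern_score))
  }
  res <- activation_axis(ps, act)
  expect_equal(res$r[1], 1, tolerance = 1e-12)
  expect_true(all(res$significant[1:4]))
  expect_true(all(res$r[2:4] < 0))
  # Independent noise activations: BH mask empty in most replicates.
  empties <- vapply(1:30, function(r) {
    set.seed(700 + r)
    a <- matrix(rnorm(n * 40), n, 40)
    !any(activation_axis(ps, a)$significant)
  }, logical(1))
  expect_gt(mean(empties), 0.8)
})
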