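test_that("weighted moments match hand-evaluated values", {
  # x = [0, 2], y = [0, 2], equal weights: mean 1, population var 1, cov 1.
  m <- weighted_moments(c(0, 2), c(0, 2), c(1, 1))
  expect_equal(m$mean_x, 1)
  expect_equal(m$var_x, 1)
  expect_equal(m$cov_xy, 1)
  # Equal weights reduce to arithmetic mean / (1/n)-normalized moments.
  x <- c(1.2, -0.4, 3.1, 0.8); y <- c(0.5, 1.5, -2, 0.1)
  m2 <- weighted_moments(x, y, rep(2.5, 4))
  expect_equal(m2$mean_x, mean(x))
  expect_equal(m2$var_x, mean((x - mean(x))^2))
  expect_equal(m2$cov_xy, mean((x - mean(x)) * (y - mean(y))))
  # Degenerate-weight limit concentrates on the surviving point.
  m3 <- weighted_moments(c(10, 0), c(0, 0), c(1, 1e-12))
  expect_equal(m3$mean_x, 10, tolerance = 1e-10)
  expect_error(weighted_moments(1:3, 1:2, c(1, 1)), "equal lengths")
  expect_error(weighted_moments(1:2, 1:2, c(1, 0)), "positive")
})

test_that("weighted correlation reduces to Pearson and handles planted case", {
  x <- rnorm(30); y <- rnorm(30)
  expect_equal(weighted_correlation(x, y, rep(3, 30)), cor(x, y))
  expect_equal(weighted_correlation(x, 2 * x + 3, runif(30, 0.5, 2)), 1)
  # Frozen hand evaluation of the weighted-moment chain:
  # x=[1,2,3], y=[1,3,2], w=[1,1,2]: mu_x=2.25, mu_y=2, var_x=0.6875,
  # var_y=0.5, cov=0.25 -> r = 0.25/sqrt(0.34375) = 0.4264014.
  expect_equal(weighted_correlation(c(1, 2, 3), c(1, 3, 2), c(1, 1, 2)),
               0.4264014, tolerance = 1e-6)
  # Rank transform with equal weights equals Spearman.
  expect_equal(weighted_correlation(x, y, rep(1, 30), rank_transform = TRUE),
               cor(x, y, method = "spearman"))
  expect_error(weighted_correlation(rep(1, 5), rnorm(5), rep(1, 5)),
               "variance")
})

test_that("PLS identities: reconstruction, normalization, reductions", {
  coh <- truth_cohort()
  x <- coh$truth$true_h; y <- as.matrix(coh$factors[, -1])
  m <- fit_pls(x, y)
  # U S V' reconstructs the cross-block covariance.
  rec <- m$brain_loadings %*% diag(m$singular_values) %*%
    t(m$design_loadings)
  expect_lt(max(abs(rec - m$cross_covariance)) /
              max(abs(m$cross_covariance)), 1e-8)
  expect_equal(sum(m$covariance_explained), 1, tolerance = 1e-10)
  expect_true(all(diff(m$singular_values) <= 1e-12))
  # Orthonormal loadings.
  expect_equal(crossprod(m$brain_loadings), diag(4), tolerance = 1e-8)
  expect_equal(crossprod(m$design_loadings), diag(4), tolerance = 1e-8)
  # Constant weights reproduce the unweighted fit exactly.
  mw <- fit_pls(x, y, weights = rep(2.7, nrow(x)))
  expect_equal(mw$brain_loadings, m$brain_loadings, tolerance = 1e-12)
  expect_equal(mw$singular_values, m$singular_values, tolerance = 1e-12)
  # Single-column outcome: one LV explaining 100%.
  m1 <- fit_pls(x, y[, 1, drop = FALSE])
  expect_equal(m1$covariance_explained, 1)
  # Sign convention: largest-|v| design loading positive.
  for (l in seq_len(4)) {
    expect_gt(m$design_loadings[which.max(abs(m$design_loadings[, l])), l], 0)
  }
})

test_that("planted loadings are recovered with design loadings on the
           expected factors", {
  coh <- truth_cohort()
  m <- truth_model()
  expect_gt(abs(cor(m$brain_loadings[, 1],
                    coh$truth$latent_brain_loadings)), 0.9)
  v1 <- m$design_loadings[, 1]
  # Largest loadings on the general and ADHD factors, as planted.
  expect_setequal(names(sort(abs(v1), decreasing = TRUE))[1:2],
                  c("general", "adhd"))
  expect_equal(m$perm_p[1], 1 / 301) # strong effect: minimum attainable
  expect_gt(min(m$perm_p[-1]), 0.05)
})

test_that("bootstrap ratios separate planted from null parcels", {
  # Custom loading vector with an explicit null block.
  load <- c(rep(1, 10), rep(0.6, 10), rep(0, 10))
  coh <- simulate_cohort(cohort_config(400, n_parcels = 30,
                                       latent_brain_loadings = load,
                                       seed = 303),
                         generate_timeseries = FALSE)
  br <- pls_bootstrap(coh$truth$true_h, coh$factors, n_boot = 400,
                      seed = 5)
  br1 <- br$brain[, 1]
  expect_gt(mean(abs(br1[1:10]) > 3), 0.8)
  # Null-parcel BRs behave like standard normal deviates.
  expect_lt(mean(abs(br1[21:30]) > 3), 0.3)
  expect_lt(abs(mean(br1[21:30])), 1.2)
})

test_that("weighted permutation reduces to unweighted under equal weights", {
  coh <- simulate_cohort(cohort_config(80, n_parcels = 12, seed = 55),
                         generate_timeseries = FALSE)
  x <- coh$truth$true_h; y <- as.matrix(coh$factors[, -1])
  p_u <- pls_permutation(x, y, n_perm = 200, seed = 99)
  p_w <- pls_permutation(x, y, weights = rep(4, 80), n_perm = 200, seed = 99)
  expect_equal(p_u, p_w)
  expect_true(all(p_u >= 1 / 201 & p_u <= 1))
})

test_that("duplicating subjects with compensating weights changes nothing", {
  coh <- simulate_cohort(cohort_config(50, n_parcels = 8, seed = 66),
                         generate_timeseries = FALSE)
  x <- coh$truth$true_h; y <- as.matrix(coh$factors[, -1])
  w <- runif(50, 0.5, 2)
  m1 <- fit_pls(x, y, w)
  m2 <- fit_pls(rbind(x, x), rbind(y, y), c(w, w) / 2)
  expect_equal(m1$brain_loadings, m2$brain_loadings, tolerance = 1e-10)
  expect_equal(m1$singular_values, m2$singular_values, tolerance = 1e-10)
})

test_that("permutation p-values are calibrated under a true null", {
  # Type-I: replicate null datasets; LV-1 rejection rate at alpha = .05.
  n_rep <- 100
  rej <- vapply(1:n_rep, function(r) {
    set.seed(4000 + r)
    x <- matrix(rnorm(60 * 10), 60, 10)
    y <- matrix(rnorm(60 * 3), 60, 3)
    pls_permutation(x, y, n_perm = 200, seed = 8000 + r)[1] <= 0.05
  }, logical(1))
  expect_lt(abs(mean(rej) - 0.05), 0.05)
})

test_that("tidy and glance summarise a fitted model", {
  m <- truth_model()
  td <- tidy(m)
  expect_tbl_names(td, c("block", "term", "lv", "loading",
                         "bootstrap_ratio"))
  expect_equal(nrow(td), (m$n_parcels + 4) * 4)
  # tidy loadings agree with the matrices.
  b1 <- dplyr::filter(td, block == "brain", lv == 1)
  expect_equal(b1$loading, unname(m$brain_loadings[, 1]))
  expect_equal(b1$bootstrap_ratio, unname(m$brain_bootstrap_ratios[, 1]))
  gl <- glance(m)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$lv1_perm_p, m$perm_p[1])
})
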