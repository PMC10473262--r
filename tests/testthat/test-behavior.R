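test_that("d-prime matches the inverse-erfc form and its symmetries", {
  # Independent oracle: invert erfc numerically and evaluate the printed
  # formula directly.
  erfc <- function(z) 2 * pnorm(-sqrt(2) * z)
  erfc_inv_num <- function(y) {
    uniroot(function(z) erfc(z) - y, c(-6, 6), tol = 1e-12)$root
  }
  d_oracle <- -2 * erfc_inv_num(2 * 0.8) + 2 * erfc_inv_num(2 * 0.2)
  expect_equal(dprime(0.8, 0.2), d_oracle, tolerance = 1e-9)
  expect_equal(dprime(0.8, 0.2), 2.380, tolerance = 1e-3)
  # hit = fa gives 0; antisymmetry under swapping.
  for (p in c(0.1, 0.37, 0.5, 0.9)) expect_equal(dprime(p, p), 0)
  g <- expand.grid(h = c(0.2, 0.5, 0.85), f = c(0.1, 0.4, 0.7))
  expect_equal(dprime(g$h, g$f), -dprime(g$f, g$h))
  # Conventional scaling divides by sqrt(2).
  expect_equal(dprime(0.8, 0.2, conventional = TRUE),
               qnorm(0.8) - qnorm(0.2))
  expect_error(dprime(1.2, 0.5), "0, 1")
})

test_that("d-prime is monotone and edge rates are clamped finitely", {
  hits <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(dprime(hits, 0.2)) > 0))
  expect_true(all(diff(dprime(0.8, hits)) < 0))
  # Edge correction: 1/(2n) when trials known, eps otherwise.
  expect_equal(dprime(1, 0.2, n_trials = 40), dprime(1 - 1 / 80, 0.2))
  expect_equal(dprime(1, 0, eps = 0.01), dprime(0.99, 0.01))
  expect_true(is.finite(dprime(1, 0)))
})

test_that("weight assembly multiplies streams and inverts probabilities", {
  expect_equal(assemble_weights(rep(1, 4))$weight, rep(1, 4))
  expect_equal(assemble_weights(c(2, 1), c(1, 3))$weight, c(2, 3))
  # Null linear predictor: inclusion probability 1/2, weights 2.
  wm <- weight_model(rep(0, 5))
  expect_equal(wm$inclusion_prob, rep(0.5, 5))
  expect_equal(assemble_weights(wm)$weight, rep(2, 5))
  # Mixed streams with provenance labels.
  out <- assemble_weights(poststrat = c(1.1, 0.9), nonpart = wm <-
                            weight_model(c(0, 0)))
  expect_equal(out$weight, c(2.2, 1.8))
  expect_equal(attr(out, "provenance"), c("poststrat", "nonpart"))
  expect_error(assemble_weights(c(1, -1)), "non-positive")
  expect_error(assemble_weights(c(1, 2), c(1, 2, 3)), "length")
})

test_that("Fisher intervals match direct evaluation and shrink with n", {
  ci <- fisher_ci(0.5, 28)
  expect_equal(ci$low, 0.1559, tolerance = 1e-3)
  expect_equal(ci$high, 0.7358, tolerance = 1e-3)
  # r = 0: symmetric about zero.
  ci0 <- fisher_ci(0, 50)
  expect_equal(ci0$low, -ci0$high)
  # Width strictly decreasing in n.
  widths <- vapply(c(10, 30, 100, 1000), function(n) {
    ci <- fisher_ci(0.4, n); ci$high - ci$low
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  expect_error(fisher_ci(1, 10), "< 1")
  expect_error(fisher_ci(0.2, 3), "n > 3")
})

test_that("Fisher interval coverage is near nominal", {
  rho <- 0.3; n <- 100
  cover <- vapply(1:1000, function(r) {
    set.seed(r)
    x <- rnorm(n); y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    ci <- fisher_ci(cor(x, y), n)
    ci$low <= rho && rho <= ci$high
  }, logical(1))
  expect_lt(abs(mean(cover) - 0.95), 0.02)
})

test_that("stratified folds partition and balance covariates", {
  set.seed(3)
  cov_tbl <- data.frame(age = rnorm(200), sex = rep(c("m", "f"), 100))
  folds <- stratified_folds(cov_tbl, k = 4, seed = 5)
  expect_setequal(unique(folds), 1:4)
  expect_equal(length(folds), 200)
  expect_true(max(table(folds)) - min(table(folds)) <= 4)
  # Binary covariate split near 50/50 within each fold at k = 2.
  f2 <- stratified_folds(cov_tbl["sex"], k = 2, seed = 6)
  tab <- table(f2, cov_tbl$sex)
  expect_true(all(abs(tab[, 1] - tab[, 2]) <= 1))
  # Stratified folds balance a continuous covariate better than random
  # folds (max deviation of fold means from the grand mean, 60 seeds).
  dev_strat <- dev_rand <- numeric(60)
  for (s in 1:60) {
    fs <- stratified_folds(cov_tbl, k = 5, seed = 100 + s)
    fr <- with_seed_local <- local({
      set.seed(100 + s); sample(rep(1:5, length.out = 200))
    })
    dev_strat[s] <- max(abs(tapply(cov_tbl$age, fs, mean)))
    dev_rand[s] <- max(abs(tapply(cov_tbl$age, fr, mean)))
  }
  expect_lt(mean(dev_strat), mean(dev_rand))
  expect_error(stratified_folds(cov_tbl, k = 500), "exceeds")
})

test_that("cross-validated PLS generalizes on a planted cohort", {
  coh <- truth_cohort()
  x <- coh$truth$true_h
  folds <- stratified_folds(
    data.frame(stratum = coh$weights$stratum,
               severity = coh$factors$general), k = 5, seed = 9)
  cv <- crossval_pls(x, coh$factors, coh$behavior, folds, coh$geometry,
                     n_surrogates = 99, seed = 10)
  expect_equal(nrow(cv), 5)
  # Every subject is left out exactly once.
  expect_equal(sum(cv$n_test), 500)
  expect_true(all(cv$loading_cor > 0.8))
  expect_true(all(cv$spin_p == 1 / 100))
  # Out-of-sample brain scores track the planted general factor; brain
  # loadings are negative where severity bites, so scores fall with
  # severity and rise with performance.
  expect_true(all(abs(cv$r_factor) > 0.2))
  expect_true(all(sign(cv$r_factor) == sign(cv$r_factor[1])))
  expect_true(all(cv$factor_low <= cv$r_factor &
                    cv$r_factor <= cv$factor_high))
  # Shuffled outcomes, benchmarked against the real full-data pattern:
  # fold loadings are noise directions, so their correlations with the
  # genuine pattern collapse toward the spin null.
  # A residual alignment remains by construction: any outcome direction
  # projected through X' picks up the brain block's dominant variance
  # direction, which is the planted map itself. So the control is judged
  # relative to the planted run: correlations collapse from ~1 and the
  # spin p rises by an order of magnitude.
  set.seed(11)
  y_perm <- coh$factors[sample.int(500), ]
  full <- fit_pls(x, coh$factors)
  cv0 <- crossval_pls(x, y_perm, coh$behavior, folds, coh$geometry,
                      full_model = full, n_surrogates = 99, seed = 12)
  expect_lt(median(cv0$loading_cor), 0.6)
  expect_gt(median(cv0$spin_p), 3 * median(cv$spin_p))
})
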