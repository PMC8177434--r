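test_that("noise-free data are interpolated exactly", {
  truth <- street_truth()
  a <- seq(0.05, 0.8, length.out = 50)
  rows <- data.frame(alpha = a, observed_use = predict_street_use(a, truth))
  fit <- fit_predictive_model(rows, "street")
  expect_true(fit$converged)
  expect_lt(fit$objective, 1e-12)
  expect_equal(fit$params$beta1, 0.9, tolerance = 1e-4)
  expect_equal(fit$params$beta2, 1.4, tolerance = 1e-4)
  expect_equal(fit$params$beta3, 0.3, tolerance = 1e-4)
})

test_that("degenerate inputs are rejected with informative errors", {
  truth <- street_truth()
  a <- seq(0.1, 0.6, length.out = 6)
  small <- data.frame(alpha = a, observed_use = predict_street_use(a, truth))
  expect_error(fit_predictive_model(small, "street"), "at least 8")
  flat <- data.frame(alpha = rep(0.3, 20), observed_use = runif(20, 0, 0.1))
  expect_error(fit_predictive_model(flat, "street"), "unidentifiable")
  mixed <- data.frame(alpha = seq(0.1, 0.5, length.out = 10),
                      observed_use = 0.05, year = rep(c(1, 2), 5))
  expect_error(fit_predictive_model(mixed, "street"), "separately")
})

test_that("fits ignore row order and any population weighting", {
  set.seed(5)
  tab <- generate_localities(synthetic_config(80, street_truth(), seed = 5))
  f1 <- fit_predictive_model(tab, "street")
  f2 <- fit_predictive_model(tab[sample(nrow(tab)), ], "street")
  expect_equal(f1$params[1:3], f2$params[1:3])
  expect_equal(f1$objective, f2$objective)
  # duplicating rows changes the (unweighted) objective: each locality is
  # one squared residual, never a population-weighted share
  dup <- rbind(tab, tab)
  f3 <- fit_predictive_model(dup, "street")
  expect_equal(2 * f1$objective, f3$objective, tolerance = 1e-6)
})

test_that("parameters are recovered from high-precision surveys, curves from noisy ones", {
  truth <- street_truth()
  # high-precision observation counts pin down all three parameters
  rel_err <- sapply(1:5, function(seed) {
    tab <- generate_localities(synthetic_config(200, truth, obs_counts = 2e5,
                                                seed = seed))
    fit <- fit_predictive_model(tab, "street")
    abs(c(fit$params$beta1, fit$params$beta2, fit$params$beta3) -
          c(0.9, 1.4, 0.3)) / c(0.9, 1.4, 0.3)
  })
  expect_true(all(apply(rel_err, 1, median) < 0.10))
  # at survey-scale noise the fitted curve still tracks the truth even
  # though (beta1, beta3) individually sit on a weakly identified ridge
  grid <- seq(0.05, 0.6, length.out = 100)
  true_curve <- predict_street_use(grid, truth)
  curve_err <- sapply(1:5, function(seed) {
    tab <- generate_localities(synthetic_config(200, truth, obs_counts = 500,
                                                seed = seed))
    fit <- fit_predictive_model(tab, "street")
    max(abs(predict_street_use(grid, fit$params) - true_curve))
  })
  expect_lt(median(curve_err), 0.02)
})

test_that("bootstrap band is ordered, seeded-reproducible, and nested across levels", {
  set.seed(9)
  tab <- generate_localities(synthetic_config(60, street_truth(), seed = 9))
  fit <- fit_predictive_model(tab, "street")
  band <- bootstrap_band(tab, "street", fit, n_boot = 199, level = 0.90,
                         seed = 99)
  expect_true(all(band$lower <= band$point + 1e-10))
  expect_true(all(band$point <= band$upper + 1e-10))
  band2 <- bootstrap_band(tab, "street", fit, n_boot = 199, level = 0.90,
                          seed = 99)
  expect_identical(band$lower, band2$lower)
  expect_identical(band$upper, band2$upper)
  # 80% band from the same replicates nests inside the 90% band
  reps <- attr(band, "replicates")
  lo80 <- apply(reps, 2, quantile, probs = 0.10, names = FALSE)
  hi80 <- apply(reps, 2, quantile, probs = 0.90, names = FALSE)
  expect_true(all(lo80 >= band$lower - 1e-12))
  expect_true(all(hi80 <= band$upper + 1e-12))
  expect_error(bootstrap_band(tab, "street", fit, n_boot = 99), "199")
})

test_that("recovery error decreases with the per-locality observation count", {
  truth <- street_truth()
  err_at_k <- sapply(c(100, 2000), function(k) {
    errs <- sapply(1:6, function(seed) {
      tab <- generate_localities(synthetic_config(200, truth, obs_counts = k,
                                                  seed = 100 + seed))
      fit <- fit_predictive_model(tab, "street")
      mean(abs(c(fit$params$beta1, fit$params$beta2, fit$params$beta3) -
                 c(0.9, 1.4, 0.3)) / c(0.9, 1.4, 0.3))
    })
    median(errs)
  })
  expect_lt(err_at_k[2], err_at_k[1])
})

test_that("nonparametric check flags misspecification and tracks flat signals", {
  set.seed(21)
  truth <- street_truth()
  tab <- generate_localities(synthetic_config(120, truth, obs_counts = 500,
                                              seed = 21))
  fit <- fit_predictive_model(tab, "street")
  band <- bootstrap_band(tab, "street", fit, n_boot = 199, seed = 22)
  np_good <- nonparametric_check(tab, band)
  expect_gte(np_good$inside_share, 0.75)

  # same alphas, but use generated from a straight line: the nonparametric
  # fit should leave the band over much more of the grid
  tab_bad <- tab
  tab_bad$observed_use <- pmin(pmax(
    0.1 * tab$alpha + rnorm(nrow(tab), 0, 0.002), 0), 1)
  fit_bad <- fit_predictive_model(tab_bad, "street")
  band_bad <- bootstrap_band(tab_bad, "street", fit_bad, n_boot = 199, seed = 23)
  np_bad <- nonparametric_check(tab_bad, band_bad)
  expect_lt(np_bad$inside_share, np_good$inside_share)

  # constant signal: local-linear fit reproduces the constant
  tab_flat <- tab
  tab_flat$observed_use <- rep(0.25, nrow(tab))
  band_flat <- band
  np_flat <- nonparametric_check(tab_flat, band_flat)
  expect_equal(np_flat$table$np_fit, rep(0.25, nrow(band_flat)),
               tolerance = 1e-8)
})
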