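test_that("empirical equilibrium function evaluates the closed form", {
  expect_equal(empirical_p_star(0.25, empirical_params(1, 1, 0.5)), 0.75)
  expect_equal(empirical_p_star(0.25, empirical_params(1, 2, 0.5)), 0.1875)
  # (1 - alpha) factor kills the function near alpha = 1 for beta2 >= 1
  expect_lt(empirical_p_star(1 - 1e-9, empirical_params(1, 2, 0.5)), 1e-8)
  # values leaving (0, 1) are flagged, not clamped
  expect_warning(out <- empirical_p_star(0.25, empirical_params(5, 1, 0.5)),
                 "outside")
  expect_equal(as.numeric(out), 3.75)
})

test_that("random-match street use reproduces the binomial-formula identity", {
  expect_equal(street_use_random_match(0.8, 1), 0.64)
  expect_equal(street_use_random_match(0.6, 0), 0)
  expect_equal(street_use_random_match(0.5, 0.5), 0.1875)
  grid <- expand.grid(a = seq(0, 1, length.out = 101),
                      p = seq(0, 1, length.out = 101))
  lhs <- grid$a^2 * grid$p^2 + 2 * grid$a^2 * grid$p * (1 - grid$p)
  expect_equal(street_use_random_match(grid$a, grid$p), lhs, tolerance = 1e-15)
})

test_that("Monte-Carlo pair simulation agrees with the random-match formula", {
  # each partner bilingual w.p. alpha; each bilingual Reveals w.p. p;
  # B is spoken iff both partners are bilingual and at least one Reveals
  set.seed(123)
  n_pairs <- 2e5
  for (case in list(c(0.5, 0.5), c(0.8, 0.3))) {
    a <- case[1]; p <- case[2]
    b1 <- runif(n_pairs) < a; b2 <- runif(n_pairs) < a
    r1 <- b1 & runif(n_pairs) < p; r2 <- b2 & runif(n_pairs) < p
    in_b <- b1 & b2 & (r1 | r2)
    mu <- street_use_random_match(a, p)
    se <- sqrt(mu * (1 - mu) / n_pairs)
    expect_lt(abs(mean(in_b) - mu), 3 * se)
  }
})

test_that("street and daily predictive models follow their absorbed forms", {
  st <- empirical_params(1, 1, 0.5, model_kind = "street")
  dl <- empirical_params(1, 1, 0.5, model_kind = "daily")
  expect_equal(predict_street_use(0.5, st), 0.125)
  expect_equal(predict_daily_use(0.5, dl), 0.25)
  # linear scale
  st2 <- empirical_params(2, 1, 0.5, model_kind = "street")
  a <- seq(0.1, 0.8, by = 0.1)
  expect_equal(predict_street_use(a, st2), 2 * predict_street_use(a, st))
  # street/daily ratio is (beta1_street / beta1_daily) * alpha throughout
  expect_equal(predict_street_use(a, st) / predict_daily_use(a, dl), a)
  expect_lt(predict_daily_use(1e-8, dl), 1e-7)
  expect_error(predict_street_use(0.5, dl), "street")
})

test_that("structural street model with c2 collapses to the right special cases", {
  a <- seq(0.1, 0.8, by = 0.05)
  # c2 = 1 with c1 = 0.5: half the pure random-match share at p* from Eq 3
  pars <- empirical_params(1, 1, 0.5, c2 = 1, c1 = 0.5, model_kind = "street")
  ps <- empirical_p_star(a, empirical_params(1, 1, 0.5))
  expect_equal(predict_street_use(a, pars),
               0.5 * street_use_random_match(a, ps))
  # c2 = 0 structural form with absorbed scale 2 * c1 * beta1 equals Eq 4
  absorbed <- empirical_params(2 * 0.5 * 1, 1, 0.5, model_kind = "street")
  expect_equal(predict_street_use(a, absorbed),
               0.5 * 2 * a^2 * ps)
})

test_that("fitted curves are increasing and convex where the bulk of localities lie", {
  # the synthetic alpha distribution concentrates below ~0.4 (median ~0.25);
  # on that range the predictive curves are increasing and convex
  set.seed(31)
  tab <- generate_localities(synthetic_config(150, street_truth(),
                                              obs_counts = 500, seed = 31))
  fit <- fit_predictive_model(tab, "street")
  a <- seq(0.03, 0.40, length.out = 150)
  y <- predict_street_use(a, fit$params)
  expect_true(all(diff(y) > 0))
  a_lo <- a[a <= 0.25]
  expect_true(all(diff(diff(predict_street_use(a_lo, fit$params))) > -1e-10))
  yd <- predict_daily_use(a, daily_truth())
  expect_true(all(diff(yd) > 0))
})

test_that("aggregation reproduces the two-locality pitfall numbers", {
  agg <- aggregate_localities(c(1, 5), c(0.8, 0.2), c(0.5, 0.02))
  expect_equal(agg$alpha, 0.3)
  expect_equal(agg$use, 0.1)
  expect_equal(random_match_ceiling(c(0.8, 0.2, agg$alpha)),
               c(0.64, 0.04, 0.09))
  # single locality aggregates to itself; constant alpha survives weighting
  expect_equal(aggregate_localities(3, 0.4, 0.2), list(alpha = 0.4, use = 0.2))
  expect_equal(aggregate_localities(c(1, 9), c(0.4, 0.4), c(0.1, 0.3))$alpha, 0.4)
  expect_error(aggregate_localities(numeric(0), numeric(0), numeric(0)),
               "no localities")
})
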