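test_that("assumption validation passes an admissible spec and flags a broken one", {
  # m = 1 + (0.9 - a), c = 0.1 * (0.9 - a): every A.3 condition holds on
  # {0.2, 0.5, 0.8} (hand-checked inequalities)
  spec <- payoff_spec(function(a) 1 + (0.9 - a), function(a) 0.1 * (0.9 - a),
                      n = 1, alpha_star = 0.9)
  report <- validate_assumptions(spec, alpha_grid = c(0.2, 0.5, 0.8))
  expect_identical(nrow(report), 0L)

  # constant c = n violates n > c > 0, monotonicity and the limit at alpha*
  broken <- payoff_spec(function(a) 1 + (0.9 - a), function(a) rep(1, length(a)),
                        n = 1, alpha_star = 0.9)
  rep2 <- validate_assumptions(broken, alpha_grid = c(0.2, 0.5, 0.8))
  expect_true("n > c(alpha) > 0" %in% rep2$condition)
  expect_true("c strictly decreasing" %in% rep2$condition)
})

test_that("validation rejects out-of-domain grids and warns on majority-bilingual aggregates", {
  spec <- lug_payoff_family()
  expect_error(validate_assumptions(spec, alpha_grid = c(0.2, 0.95)),
               "aspiration")
  expect_error(validate_assumptions(spec, alpha_grid = c(-0.1, 0.5)),
               "\\(0, 1\\)")
  expect_warning(validate_assumptions(spec, alpha_grid = c(0.3, 0.5),
                                      country_alpha = 0.55),
                 "minority")
})

test_that("expected payoffs match the game matrix arithmetic", {
  s <- example_spec()  # m = 2, n = 1, c = 0.4 at alpha = 0.5
  u <- expected_payoffs(s, 0.5, p = 1)
  expect_equal(unname(u), c(1.3, 1.5))
  u0 <- expected_payoffs(s, 0.5, p = 0)
  expect_equal(unname(u0["u_R"] - u0["u_H"]), 0.3)
  # indifference at the p solving alpha (1-p)(m-n) = (1-alpha) c
  p_ind <- 1 - (1 - 0.5) * 0.4 / (0.5 * 1)
  u_eq <- expected_payoffs(s, 0.5, p_ind)
  expect_equal(unname(u_eq["u_R"]), unname(u_eq["u_H"]), tolerance = 1e-12)
  expect_error(expected_payoffs(s, 0.5, p = 1.2), "\\[0, 1\\]")
})

test_that("weighted benefit formula and limits", {
  s <- example_spec()
  expect_equal(weighted_benefit(s, 0.5), 1.0)
  # vanishes as alpha -> 0 with bounded m
  expect_lt(weighted_benefit(lug_payoff_family(), 1e-4), 1e-3)
  # m == n everywhere gives a zero bound
  flat <- payoff_spec(function(a) rep(1, length(a)), function(a) 0.1 * (0.9 - a))
  expect_equal(weighted_benefit(flat, 0.3), 0)
  expect_error(weighted_benefit(s, 0.95), "aspiration")
})

test_that("closed-form ESS matches hand-derived values and boundary limits", {
  eq <- ess_equilibrium(example_spec(), 0.5)
  expect_equal(eq$p_star, 0.6)
  expect_equal(eq$shift_prob, 0.16)
  expect_equal(eq$use_prob_bilingual_pair, 0.84)
  expect_identical(eq$rest_points$stability, c("unstable", "stable", "unstable"))

  eq2 <- ess_equilibrium(spec_at(0.2, 3, 0.3), 0.2)
  expect_equal(eq2$p_star, 0.4)

  # zero-cost limit: p* -> 1, shift -> 0
  eq3 <- ess_equilibrium(spec_at(0.5, 2, 1e-10), 0.5)
  expect_equal(eq3$p_star, 1, tolerance = 1e-8)
  expect_lt(eq3$shift_prob, 1e-9)

  # cost at/above the weighted benefit: no interior equilibrium
  expect_error(ess_equilibrium(spec_at(0.5, 2, 1.0), 0.5), "weighted benefit")
})

test_that("equilibrium properties hold over randomized admissible specs", {
  set.seed(42)
  for (i in 1:100) {
    cs <- random_admissible_case()
    eq <- ess_equilibrium(cs$spec, cs$alpha)
    expect_gt(eq$p_star, 0)
    expect_lt(eq$p_star, 1)
    # probability closure is an algebraic identity
    expect_equal(eq$shift_prob + eq$use_prob_bilingual_pair, 1)
    # indifference at p*, strict payoff advantage on either side (ESS)
    u_at <- expected_payoffs(cs$spec, cs$alpha, eq$p_star)
    expect_equal(unname(u_at["u_R"]), unname(u_at["u_H"]), tolerance = 1e-12)
    u_lo <- expected_payoffs(cs$spec, cs$alpha, eq$p_star * 0.9)
    u_hi <- expected_payoffs(cs$spec, cs$alpha, eq$p_star + (1 - eq$p_star) * 0.1)
    expect_gt(u_lo["u_R"], u_lo["u_H"])
    expect_lt(u_hi["u_R"], u_hi["u_H"])
  }
})

test_that("comparative statics: p* rises with m and falls with c", {
  alphas <- c(0.3, 0.5, 0.7)
  for (a in alphas) {
    p_base <- ess_equilibrium(spec_at(a, 2, 0.2), a)$p_star
    expect_gt(ess_equilibrium(spec_at(a, 2.5, 0.2), a)$p_star, p_base)
    expect_lt(ess_equilibrium(spec_at(a, 2, 0.28), a)$p_star, p_base)
  }
})
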