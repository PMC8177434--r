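#' Payoff specification for the Language Use Game
#'
#' The Language Use Game (LUG) is played by the bilinguals of a locality with
#' bilingual proportion `alpha`. A bilingual who *Reveals* (strategy R) speaks
#' the minority language B with any bilingual partner and earns `m(alpha)`;
#' when matched to a monolingual she is forced to switch to the majority
#' language A and earns `n - c(alpha)`, where `c(alpha)` is a frustration
#' cost. A bilingual who *Hides* (strategy H) speaks A unless addressed in B,
#' earning `n` except against an R-player, where she earns `m(alpha)`.
#'
#' The payoff primitives must satisfy, on the domain `(0, alpha_star)`:
#' `m(alpha) > n > c(alpha) > 0`, both `m` and `c` strictly decreasing with
#' limits `n` and `0` at the aspiration level `alpha_star`, and the
#' weighted-benefit bound `c(alpha) < (m(alpha) - n) * alpha / (1 - alpha)`.
#' Use [validate_assumptions()] to check a specification on a grid.
#'
#' @param m_fn Function mapping a bilingual proportion `alpha` to `m(alpha)`,
#'   the payoff of an interaction conducted in B.
#' @param c_fn Function mapping `alpha` to `c(alpha)`, the frustration cost of
#'   a forced switch to A.
#' @param n Payoff of an interaction conducted in A; a positive constant.
#' @param alpha_star Aspiration level: the bilingual proportion at which B
#'   would be considered non-endangered. Must lie in (0, 1).
#' @param family_params Optional named list recording the parameters of a
#'   built-in family (see [lug_payoff_family()]); informational only.
#'
#' @return An object of class `"payoff_spec"`.
#' @seealso [lug_payoff_family()], [validate_assumptions()],
#'   [ess_equilibrium()]
#' @export
#' @examples
#' spec <- payoff_spec(function(a) 1 + (0.9 - a), function(a) 0.1 * (0.9 - a))
#' ess_equilibrium(spec, alpha = 0.5)
payoff_spec <- function(m_fn, c_fn, n = 1, alpha_star = 0.9,
                        family_params = NULL) {
  stopifnot(is.function(m_fn), is.function(c_fn))
  if (!is.numeric(n) || length(n) != 1L || n <= 0) {
    stop("'n' must be a single positive number", call. = FALSE)
  }
  .assert_prob(alpha_star, "alpha_star")
  structure(
    list(m_fn = m_fn, c_fn = c_fn, n = n, alpha_star = alpha_star,
         family_params = family_params),
    class = "payoff_spec"
  )
}

#' Built-in parametric payoff family
#'
#' Constructs a [payoff_spec()] from the power family
#' `m(alpha) = n + mu * (alpha_star - alpha)^a` and
#' `c(alpha) = kappa * (alpha_star - alpha)^d`, the simplest family whose
#' members are strictly decreasing on `(0, alpha_star)` with the required
#' limits `n` and `0` at the aspiration level.
#'
#' The weighted-benefit bound is not automatic for every parameter choice;
#' check with [validate_assumptions()] on the alpha range of interest.
#'
#' @param mu,a Scale and shape of the minority-language payoff premium;
#'   both positive.
#' @param kappa,d Scale and shape of the frustration cost; both positive.
#' @inheritParams payoff_spec
#' @return A `"payoff_spec"` object.
#' @export
#' @examples
#' spec <- lug_payoff_family(mu = 2.5, kappa = 0.5)
#' validate_assumptions(spec)
lug_payoff_family <- function(mu = 2.5, kappa = 0.5, a = 1, d = 1,
                              n = 1, alpha_star = 0.9) {
  stopifnot(mu > 0, kappa > 0, a > 0, d > 0)
  force(n)
  payoff_spec(
    m_fn = function(alpha) n + mu * (alpha_star - alpha)^a,
    c_fn = function(alpha) kappa * (alpha_star - alpha)^d,
    n = n, alpha_star = alpha_star,
    family_params = list(mu = mu, kappa = kappa, a = a, d = d)
  )
}

#' @export
print.payoff_spec <- function(x, ...) {
  cat("Language Use Game payoff specification\n")
  cat(sprintf("  n (payoff in A): %g   aspiration alpha*: %g\n",
              x$n, x$alpha_star))
  if (!is.null(x$family_params)) {
    cat("  family: m = n + mu*(a*-a)^a_exp, c = kappa*(a*-a)^d  [",
        paste(names(x$family_params), unlist(x$family_params),
              sep = "=", collapse = ", "), "]\n")
  }
  invisible(x)
}

.check_alpha_domain <- function(alpha, alpha_star) {
  .assert_prob(alpha, "alpha")
  if (any(alpha >= alpha_star)) {
    stop(sprintf(
      "alpha must lie below the aspiration level alpha* = %g (payoffs are only defined on (0, alpha*))",
      alpha_star), call. = FALSE)
  }
  invisible(alpha)
}

#' Weighted-benefit bound
#'
#' The largest admissible frustration cost at a given bilingual proportion:
#' `b(alpha) = (m(alpha) - n) * alpha / (1 - alpha)`. The interior
#' equilibrium of the game exists precisely when `0 < c(alpha) < b(alpha)`.
#'
#' @param spec A [payoff_spec()].
#' @param alpha Bilingual proportion(s) in `(0, alpha_star)`.
#' @return Numeric vector of bounds, one per `alpha`.
#' @export
weighted_benefit <- function(spec, alpha) {
  stopifnot(inherits(spec, "payoff_spec"))
  .check_alpha_domain(alpha, spec$alpha_star)
  (spec$m_fn(alpha) - spec$n) * alpha / (1 - alpha)
}

#' Validate the behavioural assumptions of a payoff specification
#'
#' Checks, numerically on a grid of bilingual proportions, every condition the
#' model places on the payoff primitives: `m > n`, `n > c > 0`, strict
#' monotonicity of `m` and `c`, the limits `m -> n` and `c -> 0` at the
#' aspiration level, and the weighted-benefit bound `c < b`. An aggregate
#' (country-level) bilingual proportion of 0.5 or more triggers a warning —
#' the model targets societies where bilinguals are a minority — but
#' individual localities may exceed 0.5.
#'
#' @param spec A [payoff_spec()].
#' @param alpha_grid Grid of proportions in `(0, alpha_star)` on which the
#'   pointwise conditions are evaluated. Defaults to 50 equispaced points in
#'   `(0.01 * alpha_star, 0.99 * alpha_star)`.
#' @param country_alpha Optional country-level aggregate bilingual proportion;
#'   a value `>= 0.5` raises a warning.
#' @param mono_tol Tolerance on the strict-monotonicity check.
#' @param limit_tol Tolerance on the limit checks at the aspiration level,
#'   evaluated at `alpha_star - 1e-6`.
#' @return A data frame with one row per violated condition (columns
#'   `condition`, `alpha`, `detail`); zero rows when the specification is
#'   admissible on the grid. The full pointwise pass/fail table is attached as
#'   attribute `"checks"`.
#' @export
validate_assumptions <- function(spec, alpha_grid = NULL, country_alpha = NULL,
                                 mono_tol = 1e-9, limit_tol = 1e-3) {
  stopifnot(inherits(spec, "payoff_spec"))
  as_ <- spec$alpha_star
  if (is.null(alpha_grid)) {
    alpha_grid <- seq(0.01 * as_, 0.99 * as_, length.out = 50L)
  }
  .check_alpha_domain(alpha_grid, as_)
  alpha_grid <- sort(alpha_grid)

  m <- spec$m_fn(alpha_grid)
  cc <- spec$c_fn(alpha_grid)
  n <- spec$n
  b <- (m - n) * alpha_grid / (1 - alpha_grid)

  checks <- data.frame(
    alpha = alpha_grid,
    m_gt_n = m > n,
    c_in_0_n = cc > 0 & cc < n,
    weighted_benefit = cc < b
  )

  viol <- list()
  add_viol <- function(condition, alpha, detail) {
    viol[[length(viol) + 1L]] <<- data.frame(
      condition = condition, alpha = alpha, detail = detail)
  }
  for (cond in c("m_gt_n", "c_in_0_n", "weighted_benefit")) {
    bad <- !checks[[cond]]
    if (any(bad)) {
      lab <- switch(cond,
                    m_gt_n = "m(alpha) > n",
                    c_in_0_n = "n > c(alpha) > 0",
                    weighted_benefit = "c(alpha) < b(alpha)")
      add_viol(lab, alpha_grid[bad], "pointwise condition fails")
    }
  }
  if (length(alpha_grid) > 1L) {
    dm <- diff(m); dc <- diff(cc)
    if (any(dm > -mono_tol)) {
      add_viol("m strictly decreasing", alpha_grid[-1][dm > -mono_tol],
               "non-decreasing step on grid")
    }
    if (any(dc > -mono_tol)) {
      add_viol("c strictly decreasing", alpha_grid[-1][dc > -mono_tol],
               "non-decreasing step on grid")
    }
  }
  a_lim <- as_ - 1e-6
  if (abs(spec$m_fn(a_lim) - n) > limit_tol) {
    add_viol("m(alpha) -> n at alpha*", a_lim,
             sprintf("m - n = %.3g at alpha* - 1e-6", spec$m_fn(a_lim) - n))
  }
  if (abs(spec$c_fn(a_lim)) > limit_tol) {
    add_viol("c(alpha) -> 0 at alpha*", a_lim,
             sprintf("c = %.3g at alpha* - 1e-6", spec$c_fn(a_lim)))
  }

  if (!is.null(country_alpha) && country_alpha >= 0.5) {
    warning("country-level aggregate alpha >= 0.5: the model assumes bilinguals are a minority of the total population",
            call. = FALSE)
  }

  out <- if (length(viol)) do.call(rbind, viol) else
    data.frame(condition = character(), alpha = numeric(), detail = character())
  attr(out, "checks") <- checks
  out
}

#' Expected payoffs of the Reveal and Hide strategies
#'
#' At bilingual proportion `alpha`, with a fraction `p` of the bilinguals
#' playing Reveal, the expected payoffs are
#' `u_R = alpha * m(alpha) + (1 - alpha) * (n - c(alpha))` and
#' `u_H = alpha * (p * m(alpha) + (1 - p) * n) + (1 - alpha) * n`.
#' Their difference `u_R - u_H = alpha * (1 - p) * (m - n) - (1 - alpha) * c`
#' drives the replicator dynamics.
#'
#' @inheritParams weighted_benefit
#' @param p Fraction of Reveal-players in `[0, 1]`.
#' @return Named numeric vector `c(u_R = ..., u_H = ...)`.
#' @export
expected_payoffs <- function(spec, alpha, p) {
  stopifnot(inherits(spec, "payoff_spec"), length(alpha) == 1L,
            length(p) == 1L)
  .check_alpha_domain(alpha, spec$alpha_star)
  .assert_prob(p, "p", open = FALSE)
  m <- spec$m_fn(alpha); cc <- spec$c_fn(alpha); n <- spec$n
  c(u_R = alpha * m + (1 - alpha) * (n - cc),
    u_H = alpha * (p * m + (1 - p) * n) + (1 - alpha) * n)
}

#' Evolutionarily stable equilibrium of the Language Use Game
#'
#' Closed-form unique interior Nash equilibrium, which is the game's
#' evolutionarily stable strategy (ESS):
#' `p* = 1 - (1 - alpha) * c(alpha) / (alpha * (m(alpha) - n))`.
#' In equilibrium a random match of two bilinguals who both Hide — and hence
#' converse in the majority language — occurs with probability `(1 - p*)^2`,
#' the equilibrium language-shift probability; the complementary probability
#' `p*^2 + 2 p* (1 - p*)` is that of a match involving at least one
#' Reveal-player, in which the minority language is used.
#'
#' @inheritParams weighted_benefit
#' @param alpha A single bilingual proportion in `(0, alpha_star)`.
#' @return An object of class `"ess_equilibrium"`: a list with `p_star`,
#'   `shift_prob`, `use_prob_bilingual_pair`, a `rest_points` data frame
#'   (points 0, `p_star`, 1 with stability labels), and `alpha`.
#' @export
#' @examples
#' spec <- lug_payoff_family(mu = 2.5, kappa = 0.5)
#' ess_equilibrium(spec, 0.4)
ess_equilibrium <- function(spec, alpha) {
  stopifnot(inherits(spec, "payoff_spec"), length(alpha) == 1L)
  .check_alpha_domain(alpha, spec$alpha_star)
  m <- spec$m_fn(alpha); cc <- spec$c_fn(alpha); n <- spec$n
  if (m <= n) {
    stop("m(alpha) <= n: no preference for the minority language; equilibrium undefined",
         call. = FALSE)
  }
  b <- (m - n) * alpha / (1 - alpha)
  if (cc <= 0 || cc >= b) {
    stop(sprintf(
      "c(alpha) = %.4g violates 0 < c < weighted benefit b = %.4g; the interior equilibrium would leave (0, 1)",
      cc, b), call. = FALSE)
  }
  p_star <- 1 - (1 - alpha) * cc / (alpha * (m - n))
  structure(
    list(
      p_star = p_star,
      shift_prob = (1 - p_star)^2,
      use_prob_bilingual_pair = p_star^2 + 2 * p_star * (1 - p_star),
      rest_points = data.frame(
        point = c(0, p_star, 1),
        stability = c("unstable", "stable", "unstable")
      ),
      alpha = alpha
    ),
    class = "ess_equilibrium"
  )
}

#' @export
print.ess_equilibrium <- function(x, ...) {
  cat(sprintf("LUG equilibrium at alpha = %g\n", x$alpha))
  cat(sprintf("  ESS p* (Reveal fraction): %.6f\n", x$p_star))
  cat(sprintf("  shift probability (1-p*)^2: %.6f\n", x$shift_prob))
  cat(sprintf("  B-use probability in bilingual pairs: %.6f\n",
              x$use_prob_bilingual_pair))
  invisible(x)
}
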