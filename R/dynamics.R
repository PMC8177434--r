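#' Replicator-dynamics right-hand side
#'
#' Time derivative of the Reveal fraction `p` under the replicator dynamics
#' of the Language Use Game:
#' `dp/dt = p (1 - p) [ alpha (m(alpha) - n) (1 - p) - c(alpha) (1 - alpha) ]`.
#'
#' @inheritParams weighted_benefit
#' @param p Reveal fraction(s) in `[0, 1]`.
#' @param alpha A single bilingual proportion in `(0, alpha_star)`.
#' @return Numeric vector `dp/dt`, one value per `p`.
#' @export
rd_rhs <- function(p, alpha, spec) {
  stopifnot(inherits(spec, "payoff_spec"), length(alpha) == 1L)
  .check_alpha_domain(alpha, spec$alpha_star)
  .assert_prob(p, "p", open = FALSE)
  m <- spec$m_fn(alpha); cc <- spec$c_fn(alpha); n <- spec$n
  p * (1 - p) * (alpha * (m - n) * (1 - p) - cc * (1 - alpha))
}

#' Integrate the replicator dynamics to its steady state
#'
#' Integrates the scalar replicator ODE from an interior starting fraction
#' `p0` with an adaptive solver, stopping when `|dp/dt|` falls below
#' `steady_tol` or the horizon is reached. For any admissible payoff
#' specification the trajectory converges to the interior ESS `p*` of
#' [ess_equilibrium()], which is a global attractor in `(0, 1)`; the boundary
#' rest points 0 and 1 are unstable and excluded as starting values.
#'
#' @inheritParams rd_rhs
#' @param p0 Initial Reveal fraction, strictly inside `(0, 1)`.
#' @param horizon Integration horizon (model time units).
#' @param n_steps Number of output time points.
#' @param steady_tol Steady-state stopping rule on `|dp/dt|`.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return An object of class `"rd_trajectory"`: a data frame with columns
#'   `time` and `p`, plus attributes `alpha` and `converged_to` (the terminal
#'   value).
#' @export
#' @examples
#' spec <- lug_payoff_family()
#' tr <- integrate_rd(0.05, alpha = 0.4, spec = spec)
#' attr(tr, "converged_to")
integrate_rd <- function(p0, alpha, spec, horizon = 2000, n_steps = 400L,
                         steady_tol = 1e-12, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(spec, "payoff_spec"), length(p0) == 1L)
  if (!is.numeric(p0) || p0 <= 0 || p0 >= 1) {
    stop("p0 must lie strictly inside (0, 1): the boundary points are rest points and the convergence result assumes an interior start",
         call. = FALSE)
  }
  .check_alpha_domain(alpha, spec$alpha_star)
  m <- spec$m_fn(alpha); cc <- spec$c_fn(alpha); n <- spec$n
  rhs <- function(t, y, parms) {
    p <- min(max(y[1], 0), 1)
    list(p * (1 - p) * (alpha * (m - n) * (1 - p) - cc * (1 - alpha)))
  }
  root <- function(t, y, parms) {
    p <- min(max(y[1], 0), 1)
    abs(p * (1 - p) * (alpha * (m - n) * (1 - p) - cc * (1 - alpha))) -
      steady_tol
  }
  times <- seq(0, horizon, length.out = n_steps)
  sol <- deSolve::lsodar(y = c(p = p0), times = times, func = rhs,
                         rootfunc = root, rtol = rtol, atol = atol)
  out <- data.frame(time = sol[, "time"], p = pmin(pmax(sol[, "p"], 0), 1))
  structure(out,
            class = c("rd_trajectory", "data.frame"),
            alpha = alpha,
            converged_to = out$p[nrow(out)])
}

#' Classify the rest points of the replicator dynamics
#'
#' The replicator equation of the Language Use Game has exactly three rest
#' points: 0, the interior ESS `p*`, and 1. Stability is determined by the
#' sign of the flow in punctured neighbourhoods of radius `eps`: `p*` attracts
#' from both sides while 0 and 1 repel.
#'
#' @inheritParams rd_rhs
#' @param eps Radius of the punctured neighbourhood used for the sign checks.
#' @return Data frame with columns `point` and `stability`.
#' @export
classify_rest_points <- function(alpha, spec, eps = 1e-4) {
  eq <- ess_equilibrium(spec, alpha)
  p_star <- eq$p_star
  stab_at <- function(p) {
    lo <- max(p - eps, 0); hi <- min(p + eps, 1)
    left_in <- p <= 0 || rd_rhs(lo, alpha, spec) > 0
    right_in <- p >= 1 || rd_rhs(hi, alpha, spec) < 0
    if (left_in && right_in) "stable" else "unstable"
  }
  data.frame(
    point = c(0, p_star, 1),
    stability = vapply(c(0, p_star, 1), stab_at, character(1))
  )
}

#' Finite-population state for the imitation simulator
#'
#' @param n_agents Number of bilingual agents (at least 2).
#' @param n_revealers Initial count of agents playing Reveal.
#' @param alpha Probability that a random interaction partner is bilingual.
#' @param rng_seed Integer seed making the simulation reproducible.
#' @return An object of class `"abm_state"`.
#' @seealso [simulate_abm()]
#' @export
abm_state <- function(n_agents, n_revealers, alpha, rng_seed = 1L) {
  stopifnot(n_agents >= 2, n_revealers >= 0, n_revealers <= n_agents)
  .assert_prob(alpha, "alpha")
  structure(list(n_agents = as.integer(n_agents),
                 n_revealers = as.integer(n_revealers),
                 alpha = alpha, rng_seed = as.integer(rng_seed)),
            class = "abm_state")
}

#' Simulate finite-population proportional-imitation dynamics
#'
#' A stochastic, finite-population counterpart of the replicator dynamics.
#' Each round two distinct agents — a focal agent and a role model — are
#' drawn uniformly at random. Each realises the payoff of one interaction
#' with an independent random partner whose type is bilingual with
#' probability `alpha` (types are private information, so only the realised
#' payoff is observed): a Reveal-player earns `m(alpha)` against a bilingual
#' and `n - c(alpha)` against a monolingual; a Hide-player earns `m(alpha)`
#' against a bilingual Reveal-player and `n` otherwise. The focal agent then
#' copies the role model's strategy with probability proportional to the
#' positive part of the payoff difference, normalised by the payoff range
#' `m - (n - c)`. The mean-field limit of this update rule is exactly the
#' replicator equation, so for large populations the Reveal fraction settles
#' around the ESS `p*`.
#'
#' @param state An [abm_state()].
#' @param spec A [payoff_spec()].
#' @param n_rounds Number of imitation rounds.
#' @return Integer vector of length `n_rounds + 1` with the Reveal count
#'   after each round (element 1 is the initial count). Attribute
#'   `"terminal_fraction"` holds the final Reveal fraction.
#' @export
simulate_abm <- function(state, spec, n_rounds = 1e5L) {
  stopifnot(inherits(state, "abm_state"), inherits(spec, "payoff_spec"),
            n_rounds >= 1)
  if (state$n_agents < 2) stop("need at least 2 agents", call. = FALSE)
  alpha <- state$alpha
  .check_alpha_domain(alpha, spec$alpha_star)
  m <- spec$m_fn(alpha); cc <- spec$c_fn(alpha); n <- spec$n
  span <- m - (n - cc)   # widest possible payoff gap
  N <- state$n_agents
  n_rounds <- as.integer(n_rounds)

  .with_seed(state$rng_seed, {
    u <- matrix(runif(7L * n_rounds), nrow = 7L)
    out <- integer(n_rounds + 1L)
    nR <- state$n_revealers
    out[1L] <- nR
    for (r in seq_len(n_rounds)) {
      p_now <- nR / N
      focal_R <- u[1L, r] < p_now
      model_R <- u[2L, r] < (nR - focal_R) / (N - 1)
      # realised payoff of one interaction each, against an independent
      # random partner (bilingual w.p. alpha; if bilingual, Reveal w.p. p)
      pi_f <- if (u[3L, r] < alpha) {
        if (focal_R || u[4L, r] < p_now) m else n
      } else if (focal_R) n - cc else n
      pi_m <- if (u[5L, r] < alpha) {
        if (model_R || u[6L, r] < p_now) m else n
      } else if (model_R) n - cc else n
      if (focal_R != model_R && pi_m > pi_f &&
          u[7L, r] < (pi_m - pi_f) / span) {
        nR <- nR + if (model_R) 1L else -1L
      }
      out[r + 1L] <- nR
    }
    structure(out, terminal_fraction = nR / N)
  })
}
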