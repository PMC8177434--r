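# Payoff specification whose m and c hit prescribed values at one alpha,
# via linear-in-alpha functions with the required limits at alpha_star.
spec_at <- function(alpha, m, cc, n = 1, alpha_star = 0.9) {
  force(alpha); force(m); force(cc); force(n); force(alpha_star)
  payoff_spec(
    m_fn = function(a) n + (m - n) * (alpha_star - a) / (alpha_star - alpha),
    c_fn = function(a) cc * (alpha_star - a) / (alpha_star - alpha),
    n = n, alpha_star = alpha_star
  )
}

# Random spec + alpha that is admissible at that alpha: m > n and
# 0 < c < min(n, weighted benefit b(alpha)).
random_admissible_case <- function() {
  alpha_star <- 0.9
  alpha <- runif(1, 0.05, 0.8 * alpha_star)
  n <- 1
  m <- n + runif(1, 0.2, 3)
  b <- (m - n) * alpha / (1 - alpha)
  cc <- runif(1, 0.05, 0.95) * min(n, b)
  list(spec = spec_at(alpha, m, cc, n = n, alpha_star = alpha_star),
       alpha = alpha, m = m, cc = cc, n = n)
}

# Canonical worked example used across modules
example_spec <- function() spec_at(0.5, 2, 0.4)

street_truth <- function() empirical_params(0.9, 1.4, 0.3, model_kind = "street")
daily_truth <- function() empirical_params(0.6, 1.4, 0.3, model_kind = "daily")
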