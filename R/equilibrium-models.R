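#' Empirical model parameters
#'
#' Parameters of the empirical equilibrium function and the derived
#' predictive models of minority-language use. `beta1` is the positive scale
#' parameter: for the equilibrium function it is the raw scale; for the
#' street-use model it is the absorbed scale (2 * c1 * beta1) and for the
#' daily-use model the absorbed scale (c0 * beta1) — the underlying scale
#' cannot be separately identified from use data, so it is never estimated on
#' its own. `beta2` is a free shape exponent; `beta3` in (0, 1) is the
#' aspiration-linked shape parameter (it drifts towards 0 as bilinguals'
#' aspirations rise); `c2` in [0, 1] adjusts the weight of
#' militant-militant pairs in the street-use model (0 by default, the value
#' that fits observed street-use data well; 1 recovers pure random matching
#' together with `c1 = 1`).
#'
#' @param beta1 Positive scale parameter (absorbed form for street/daily).
#' @param beta2 Shape exponent (unrestricted; values beyond +-10 are flagged
#'   by the fitting routine).
#' @param beta3 Aspiration-linked shape parameter in (0, 1).
#' @param c2 Militant-pairing adjustment in [0, 1]; only used by the
#'   street-use model.
#' @param c1 Optional street-survey scale constant, needed only when
#'   `c2 > 0` (with `c2 = 0` it is absorbed into `beta1`).
#' @param model_kind One of `"equilibrium"`, `"street"`, `"daily"`.
#' @return An object of class `"empirical_params"`.
#' @export
empirical_params <- function(beta1, beta2, beta3, c2 = 0, c1 = NULL,
                             model_kind = c("equilibrium", "street", "daily")) {
  model_kind <- match.arg(model_kind)
  if (!is.numeric(beta1) || beta1 <= 0) {
    stop("beta1 must be positive", call. = FALSE)
  }
  .assert_prob(beta3, "beta3")
  if (!is.numeric(c2) || c2 < 0 || c2 > 1) {
    stop("c2 must lie in [0, 1]", call. = FALSE)
  }
  if (c2 > 0 && model_kind == "street" && is.null(c1)) {
    stop("c1 must be supplied when c2 > 0: the absorbed scale only applies to c2 = 0",
         call. = FALSE)
  }
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 c2 = c2, c1 = c1, model_kind = model_kind),
            class = "empirical_params")
}

#' @export
print.empirical_params <- function(x, ...) {
  lab <- switch(x$model_kind,
                equilibrium = "equilibrium function p*(alpha)",
                street = "street-use model",
                daily = "daily-use model")
  cat(sprintf("Empirical %s parameters:\n", lab))
  cat(sprintf("  beta1 = %.6g, beta2 = %.6g, beta3 = %.6g",
              x$beta1, x$beta2, x$beta3))
  if (x$model_kind == "street") cat(sprintf(", c2 = %g", x$c2))
  cat("\n")
  invisible(x)
}

# Shared basis of the empirical equilibrium function:
# (1 - alpha) * (alpha^beta3 - alpha)^(beta2 - 1).
# The inner term alpha^beta3 - alpha is strictly positive on (0, 1) for
# beta3 in (0, 1), which keeps real powers well defined.
.shift_basis <- function(alpha, beta2, beta3) {
  inner <- alpha^beta3 - alpha
  if (any(inner <= 0)) {
    stop("inner term alpha^beta3 - alpha must be positive; requires alpha in (0, 1) and beta3 in (0, 1)",
         call. = FALSE)
  }
  (1 - alpha) * inner^(beta2 - 1)
}

#' Empirical equilibrium function
#'
#' The fitted form of the evolutionarily stable Reveal fraction as a function
#' of the bilingual proportion:
#' `p*(alpha) = beta1 * (1 - alpha) * (alpha^beta3 - alpha)^(beta2 - 1)`.
#'
#' @param alpha Bilingual proportion(s) in (0, 1).
#' @param params An [empirical_params()] object.
#' @return Numeric vector of equilibrium Reveal fractions. A warning is
#'   issued (and attribute `"outside_unit"` attached) when any value leaves
#'   `(0, 1)`; values are not clamped.
#' @export
#' @examples
#' pars <- empirical_params(1, 2, 0.5)
#' empirical_p_star(0.25, pars)  # 0.75 * (0.5 - 0.25) = 0.1875
empirical_p_star <- function(alpha, params) {
  stopifnot(inherits(params, "empirical_params"))
  .assert_prob(alpha, "alpha")
  out <- params$beta1 * .shift_basis(alpha, params$beta2, params$beta3)
  bad <- out <= 0 | out >= 1
  if (any(bad)) {
    warning(sprintf("%d of %d equilibrium values fall outside (0, 1); check parameters",
                    sum(bad), length(out)), call. = FALSE)
    attr(out, "outside_unit") <- which(bad)
  }
  out
}

#' Street-use share under pure random matching
#'
#' Expected share of street conversations held in the minority language when
#' all matches are uniformly random: the minority language is recorded
#' exactly when both partners are bilingual and at least one of them is a
#' Reveal-player, giving
#' `alpha^2 p*^2 + 2 alpha^2 p* (1 - p*) = 2 alpha^2 p* - alpha^2 p*^2`.
#'
#' @param alpha Bilingual proportion(s) in [0, 1].
#' @param p_star Equilibrium Reveal fraction(s) in [0, 1].
#' @return Expected street-use share(s).
#' @export
street_use_random_match <- function(alpha, p_star) {
  .assert_prob(alpha, "alpha", open = FALSE)
  .assert_prob(p_star, "p_star", open = FALSE)
  2 * alpha^2 * p_star - alpha^2 * p_star^2
}

#' Random-matching ceiling on street use
#'
#' The largest street-use share compatible with uniformly random matching:
#' all bilingual-bilingual pairs converse in the minority language, i.e.
#' `alpha^2` (the `p* = 1` case of [street_use_random_match()]). Observed
#' shares below this ceiling in a locality are the footprint of language
#' shift; comparing the ceiling of aggregated proportions with per-locality
#' ceilings shows why aggregation masks shift (see [aggregate_localities()]).
#'
#' @param alpha Bilingual proportion(s) in [0, 1].
#' @return `alpha^2`.
#' @export
random_match_ceiling <- function(alpha) {
  .assert_prob(alpha, "alpha", open = FALSE)
  alpha^2
}

#' Predicted street use of the minority language
#'
#' With the default `c2 = 0` the model is the absorbed-scale form
#' `PKE(alpha) = beta1 * alpha^2 * (1 - alpha) * (alpha^beta3 - alpha)^(beta2 - 1)`
#' (`beta1` here standing for the absorbed scale 2 * c1 * raw scale). With
#' `c2 > 0` the structural form
#' `c1 * (2 alpha^2 p* - c2 alpha^2 p*^2)` is used, with `p*` from
#' [empirical_p_star()] at the raw `beta1`.
#'
#' @inheritParams empirical_p_star
#' @param clamp If `TRUE`, predictions are clamped to [0, 1] and a logical
#'   attribute `"clamped"` marks affected entries; during fitting predictions
#'   are never clamped (clamping would bias least squares).
#' @return Predicted street-use share(s).
#' @export
predict_street_use <- function(alpha, params, clamp = FALSE) {
  stopifnot(inherits(params, "empirical_params"))
  if (params$model_kind != "street") {
    stop("params$model_kind must be 'street'", call. = FALSE)
  }
  .assert_prob(alpha, "alpha")
  out <- if (params$c2 == 0) {
    params$beta1 * alpha^2 * .shift_basis(alpha, params$beta2, params$beta3)
  } else {
    ps <- params$beta1 * .shift_basis(alpha, params$beta2, params$beta3)
    params$c1 * (2 * alpha^2 * ps - params$c2 * alpha^2 * ps^2)
  }
  .maybe_clamp(out, clamp)
}

#' Predicted daily use of the minority language
#'
#' `PDU(alpha) = beta1 * alpha * (1 - alpha) * (alpha^beta3 - alpha)^(beta2 - 1)`,
#' `beta1` standing for the absorbed scale c0 * raw scale: a Reveal-player
#' reports daily use of the minority language, a Hide-player (mostly) does
#' not, so predicted daily use is proportional to `alpha * p*(alpha)`.
#'
#' @inheritParams predict_street_use
#' @return Predicted daily-use share(s).
#' @export
predict_daily_use <- function(alpha, params, clamp = FALSE) {
  stopifnot(inherits(params, "empirical_params"))
  if (params$model_kind != "daily") {
    stop("params$model_kind must be 'daily'", call. = FALSE)
  }
  .assert_prob(alpha, "alpha")
  out <- params$beta1 * alpha * .shift_basis(alpha, params$beta2, params$beta3)
  .maybe_clamp(out, clamp)
}

.maybe_clamp <- function(x, clamp) {
  bad <- x < 0 | x > 1
  if (any(bad)) {
    warning(sprintf("%d prediction(s) outside [0, 1]", sum(bad)),
            call. = FALSE)
    if (clamp) {
      x <- pmin(pmax(x, 0), 1)
      attr(x, "clamped") <- bad
    }
  }
  x
}

#' Population-weighted aggregation of locality tables
#'
#' Population-weighted means of the bilingual proportion and of observed use
#' across localities. Aggregation is a known pitfall: two localities with
#' `(weight, alpha, use)` of (1, 0.8, 0.5) and (5, 0.2, 0.02) aggregate to
#' `alpha = 0.3`, `use = 0.1` — above the aggregate random-matching ceiling
#' `0.3^2 = 0.09`, hiding the strong per-locality shift visible against the
#' local ceilings 0.64 and 0.04.
#'
#' @param weights Positive population weights.
#' @param alpha Bilingual proportions in [0, 1].
#' @param use Observed use shares in [0, 1].
#' @return Named list with `alpha` and `use`, the weighted means.
#' @export
#' @examples
#' aggregate_localities(c(1, 5), c(0.8, 0.2), c(0.5, 0.02))
aggregate_localities <- function(weights, alpha, use) {
  if (length(weights) == 0L) stop("no localities to aggregate", call. = FALSE)
  if (length(alpha) != length(weights) || length(use) != length(weights)) {
    stop("weights, alpha and use must have equal length", call. = FALSE)
  }
  if (any(weights <= 0)) stop("weights must be positive", call. = FALSE)
  .assert_prob(alpha, "alpha", open = FALSE)
  .assert_prob(use, "use", open = FALSE)
  list(alpha = sum(weights * alpha) / sum(weights),
       use = sum(weights * use) / sum(weights))
}
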