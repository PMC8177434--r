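#' Configuration for the synthetic locality-table generator
#'
#' Describes a synthetic survey of one language in one year: `n_localities`
#' localities whose bilingual proportions are drawn from a Beta distribution
#' stretched onto `(alpha_min, alpha_max)` (right-skewed by default, placing
#' most mass at low bilingual proportions as observed survey tables do),
#' whose true use levels follow the predictive model at `true_params`, and
#' whose observed use carries binomial observation noise: street use is
#' estimated from `obs_counts` recorded conversations per locality, daily use
#' from `obs_counts` survey respondents.
#'
#' @param n_localities Number of localities L.
#' @param true_params [empirical_params()] with `model_kind` `"street"` or
#'   `"daily"`; the generating truth.
#' @param obs_counts Per-locality observation count(s) k (conversations or
#'   respondents); scalar or length-L vector.
#' @param alpha_shape1,alpha_shape2 Beta shape parameters of the alpha
#'   distribution (defaults 2 and 5: right-skewed).
#' @param alpha_min,alpha_max Support of the stretched alpha distribution;
#'   keep `alpha_max` below the aspiration level.
#' @param noise `"binomial"` (survey counts; the default) or `"gaussian"`
#'   (additive noise of sd `noise_sd`, for robustness experiments).
#' @param noise_sd Standard deviation of the optional additive noise.
#' @param seed Integer seed; generation is fully reproducible.
#' @param year_label Integer survey-year tag.
#' @param alpha_override,use_override Optional fixed vectors (length
#'   `n_localities`) that replace the drawn alphas and/or the observed use —
#'   hooks for reconstructing textbook configurations exactly.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_localities,
                             true_params,
                             obs_counts = 500L,
                             alpha_shape1 = 2, alpha_shape2 = 5,
                             alpha_min = 0.02, alpha_max = 0.88,
                             noise = c("binomial", "gaussian"),
                             noise_sd = 0.01,
                             seed = 1L,
                             year_label = 1L,
                             alpha_override = NULL,
                             use_override = NULL) {
  noise <- match.arg(noise)
  stopifnot(n_localities >= 1, all(obs_counts >= 1),
            inherits(true_params, "empirical_params"),
            alpha_shape1 > 0, alpha_shape2 > 0,
            alpha_min > 0, alpha_max < 1, alpha_min < alpha_max)
  if (!true_params$model_kind %in% c("street", "daily")) {
    stop("true_params$model_kind must be 'street' or 'daily'", call. = FALSE)
  }
  if (!length(obs_counts) %in% c(1L, n_localities)) {
    stop("obs_counts must be a scalar or one count per locality", call. = FALSE)
  }
  structure(
    list(n_localities = as.integer(n_localities), true_params = true_params,
         obs_counts = as.integer(obs_counts),
         alpha_shape1 = alpha_shape1, alpha_shape2 = alpha_shape2,
         alpha_min = alpha_min, alpha_max = alpha_max,
         noise = noise, noise_sd = noise_sd,
         seed = as.integer(seed), year_label = as.integer(year_label),
         alpha_override = alpha_override, use_override = use_override),
    class = "synthetic_config"
  )
}

#' Generate a synthetic locality survey table
#'
#' Draws bilingual proportions, evaluates the true predictive curve, and adds
#' binomial observation noise: `observed_use = Binomial(k, mu) / k` with `mu`
#' the true use level and `k` the locality's observation count. The true use
#' levels are attached as attribute `"true_use"` (a side channel for recovery
#' experiments); the table itself carries only what a real survey would
#' report, so estimation code cannot leak the truth.
#'
#' @param config A [synthetic_config()].
#' @return Data frame with columns `locality_id`, `year`, `n_bilinguals`,
#'   `alpha`, `observed_use`, `use_kind`; attribute `"true_use"` holds the
#'   noise-free use levels.
#' @export
#' @examples
#' pars <- empirical_params(0.9, 1.4, 0.3, model_kind = "street")
#' tab <- generate_localities(synthetic_config(20, pars, seed = 7))
#' head(tab)
generate_localities <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  L <- config$n_localities
  k <- rep_len(config$obs_counts, L)
  pred_fn <- if (config$true_params$model_kind == "street")
    predict_street_use else predict_daily_use

  .with_seed(config$seed, {
    alpha <- if (!is.null(config$alpha_override)) {
      stopifnot(length(config$alpha_override) == L)
      config$alpha_override
    } else {
      config$alpha_min + (config$alpha_max - config$alpha_min) *
        rbeta(L, config$alpha_shape1, config$alpha_shape2)
    }
    .assert_prob(alpha, "alpha")
    mu <- suppressWarnings(pred_fn(alpha, config$true_params))
    clipped <- mu < 0 | mu > 1
    if (mean(clipped) > 0.05) {
      stop(sprintf("true use curve leaves [0, 1] on %.0f%% of localities; choose saner true parameters",
                   100 * mean(clipped)), call. = FALSE)
    }
    if (any(clipped)) {
      warning(sprintf("%d true use value(s) clipped into [0, 1]", sum(clipped)),
              call. = FALSE)
      mu <- pmin(pmax(mu, 0), 1)
    }
    observed <- if (!is.null(config$use_override)) {
      stopifnot(length(config$use_override) == L)
      config$use_override
    } else if (config$noise == "binomial") {
      rbinom(L, k, mu) / k
    } else {
      pmin(pmax(mu + rnorm(L, 0, config$noise_sd), 0), 1)
    }
    out <- data.frame(
      locality_id = sprintf("L%04d", seq_len(L)),
      year = config$year_label,
      n_bilinguals = k,
      alpha = alpha,
      observed_use = observed,
      use_kind = config$true_params$model_kind,
      stringsAsFactors = FALSE
    )
    attr(out, "true_use") <- mu
    out
  })
}

#' Generate a multi-year synthetic panel
#'
#' Concatenates one generated table per configuration, one configuration per
#' survey year. Alpha drift across years — e.g. the thinning-out of
#' localities with very low bilingual proportions — is expressed by giving
#' later years shifted alpha distributions in their configurations.
#'
#' @param configs List of [synthetic_config()] objects with distinct
#'   `year_label`s.
#' @return Data frame stacking the per-year tables; attribute `"true_use"`
#'   stacks the per-year true curves.
#' @export
generate_panel <- function(configs) {
  stopifnot(length(configs) >= 1,
            all(vapply(configs, inherits, logical(1), "synthetic_config")))
  tabs <- lapply(configs, generate_localities)
  out <- do.call(rbind, tabs)
  if (anyDuplicated(out[, c("year", "locality_id")])) {
    stop("duplicated (year, locality_id) keys across configurations",
         call. = FALSE)
  }
  attr(out, "true_use") <- unlist(lapply(tabs, attr, "true_use"),
                                  use.names = FALSE)
  rownames(out) <- NULL
  out
}
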