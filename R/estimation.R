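# --- internal fitting machinery ---------------------------------------------

# Basis g(alpha; beta2, beta3) such that the model is beta1 * g:
# street: alpha^2 (1-alpha) (alpha^beta3 - alpha)^(beta2-1)
# daily:  alpha   (1-alpha) (alpha^beta3 - alpha)^(beta2-1)
.model_basis <- function(alpha, beta2, beta3, model_kind) {
  lead <- if (model_kind == "street") alpha^2 else alpha
  lead * (1 - alpha) * (alpha^beta3 - alpha)^(beta2 - 1)
}

# The model is linear in beta1 given (beta2, beta3), so beta1 is profiled
# out in closed form (positivity enforced) and the numerical search runs
# over (beta2, beta3) only.
.profile_beta1 <- function(g, y) {
  den <- sum(g^2)
  if (!is.finite(den) || den <= 0) return(NA_real_)
  max(sum(g * y) / den, 1e-12)
}

.fit_objective <- function(theta, alpha, y, model_kind) {
  g <- .model_basis(alpha, theta[1], theta[2], model_kind)
  if (!all(is.finite(g))) return(1e10)
  b1 <- .profile_beta1(g, y)
  if (!is.finite(b1)) return(1e10)
  rss <- sum((y - b1 * g)^2)
  if (!is.finite(rss)) 1e10 else rss
}

.default_starts <- function() {
  expand.grid(beta2 = c(0.8, 1.5, 3), beta3 = c(0.15, 0.45, 0.8))
}

.beta2_bound <- 10

.fit_once <- function(alpha, y, model_kind, start) {
  opt <- optim(
    par = c(start$beta2, start$beta3),
    fn = .fit_objective, alpha = alpha, y = y, model_kind = model_kind,
    method = "L-BFGS-B",
    lower = c(-.beta2_bound, 1e-4), upper = c(.beta2_bound, 1 - 1e-4),
    control = list(maxit = 500L)
  )
  g <- .model_basis(alpha, opt$par[1], opt$par[2], model_kind)
  list(beta1 = .profile_beta1(g, y), beta2 = opt$par[1], beta3 = opt$par[2],
       objective = opt$value, convergence = opt$convergence,
       message = opt$message)
}

.check_rows <- function(rows, min_rows = 8L) {
  need <- c("alpha", "observed_use")
  missing_cols <- setdiff(need, names(rows))
  if (length(missing_cols)) {
    stop("rows must contain columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(rows) < min_rows) {
    stop(sprintf("at least %d localities are required for a stable fit (got %d)",
                 min_rows, nrow(rows)), call. = FALSE)
  }
  if ("year" %in% names(rows) && length(unique(rows$year)) > 1L) {
    stop("rows span multiple survey years; fit each year separately",
         call. = FALSE)
  }
  if ("use_kind" %in% names(rows) && length(unique(rows$use_kind)) > 1L) {
    stop("rows mix use kinds (street/daily)", call. = FALSE)
  }
  .assert_prob(rows$alpha, "alpha")
  .assert_prob(rows$observed_use, "observed_use", open = FALSE)
  if (diff(range(rows$alpha)) < 1e-10) {
    stop("all localities share the same alpha: model parameters are unidentifiable",
         call. = FALSE)
  }
  invisible(rows)
}

#' Fit a predictive use model to a locality table
#'
#' Constrained nonlinear least squares for the street-use or daily-use model:
#' minimises the unweighted residual sum of squares
#' `sum_i (use_i - model(alpha_i; beta))^2` over `beta1 > 0`,
#' `beta3 in (0, 1)` and unrestricted `beta2` (a guard bound `|beta2| <= 10`
#' prevents optimizer escape and triggers a warning when active). Localities
#' are never weighted by population: every locality contributes one squared
#' residual. Because the model is linear in `beta1` given the shape
#' parameters, `beta1` is concentrated out analytically and a multi-start
#' box-constrained quasi-Newton search runs over `(beta2, beta3)`; the best
#' of the multi-start solutions is returned.
#'
#' @param rows Data frame of locality records: columns `alpha` and
#'   `observed_use` are required; `year` and `use_kind`, when present, must
#'   be constant across rows (fitting is per year, per language).
#' @param model_kind `"street"` or `"daily"`.
#' @param starts Optional data frame of starting values with columns `beta2`
#'   and `beta3`; defaults to a 3 x 3 grid.
#' @return An object of class `"lug_fit"`: list with `params` (an
#'   [empirical_params()]), `objective` (RSS), `converged`, `diagnostics`,
#'   `n_localities`, `model_kind` and the fitted `data`.
#' @export
#' @examples
#' pars <- empirical_params(0.9, 1.4, 0.3, model_kind = "street")
#' a <- seq(0.05, 0.8, length.out = 40)
#' rows <- data.frame(alpha = a, observed_use = predict_street_use(a, pars))
#' fit_predictive_model(rows, "street")
fit_predictive_model <- function(rows, model_kind = c("street", "daily"),
                                 starts = NULL) {
  model_kind <- match.arg(model_kind)
  rows <- as.data.frame(rows)
  .check_rows(rows)
  if (is.null(starts)) starts <- .default_starts()
  stopifnot(all(c("beta2", "beta3") %in% names(starts)))

  fits <- lapply(seq_len(nrow(starts)), function(i) {
    .fit_once(rows$alpha, rows$observed_use, model_kind, starts[i, ])
  })
  objs <- vapply(fits, `[[`, numeric(1), "objective")
  best <- fits[[which.min(objs)]]

  if (abs(best$beta2) >= .beta2_bound - 1e-6) {
    warning("beta2 estimate sits on the guard bound |beta2| = 10; the fit may be poorly identified",
            call. = FALSE)
  }
  structure(
    list(
      params = empirical_params(best$beta1, best$beta2, best$beta3,
                                model_kind = model_kind),
      objective = best$objective,
      converged = best$convergence == 0L,
      diagnostics = list(convergence = best$convergence,
                         message = best$message,
                         n_starts = nrow(starts),
                         start_objectives = objs),
      n_localities = nrow(rows),
      model_kind = model_kind,
      data = rows,
      band = NULL,
      np_check = NULL
    ),
    class = "lug_fit"
  )
}

#' @export
print.lug_fit <- function(x, ...) {
  cat(sprintf("Predictive %s-use model fit (%d localities)\n",
              x$model_kind, x$n_localities))
  print(x$params)
  cat(sprintf("  RSS: %.6g   converged: %s\n", x$objective, x$converged))
  if (!is.null(x$band)) {
    cat(sprintf("  bootstrap band: %d%% pointwise, %d replicates\n",
                round(100 * attr(x$band, "level")), attr(x$band, "n_boot")))
  }
  invisible(x)
}

#' Predict from a fitted use model
#'
#' @param object A [fit_predictive_model()] result.
#' @param alpha Bilingual proportions at which to predict; defaults to a
#'   50-point grid over the fitted data's alpha range.
#' @param clamp Clamp user-facing predictions to [0, 1] (flagged).
#' @param ... Unused.
#' @return Data frame with columns `alpha` and `predicted`.
#' @export
predict.lug_fit <- function(object, alpha = NULL, clamp = TRUE, ...) {
  if (is.null(alpha)) {
    alpha <- seq(min(object$data$alpha), max(object$data$alpha),
                 length.out = 50L)
  }
  fn <- if (object$model_kind == "street") predict_street_use else
    predict_daily_use
  data.frame(alpha = alpha, predicted = fn(alpha, object$params, clamp = clamp))
}

#' Pairs-bootstrap confidence band for a fitted use model
#'
#' Localities are the sampling unit and the observation noise is
#' heteroscedastic by construction (binomial counts of varying size), so the
#' band resamples whole localities with replacement (pairs/case bootstrap),
#' refits the model on each replicate — warm-started at the point estimates —
#' and takes pointwise percentile intervals of the replicate prediction
#' curves on an alpha grid. The band is pointwise, not simultaneous.
#'
#' @param rows Locality table used for the original fit.
#' @param model_kind `"street"` or `"daily"`.
#' @param fit The [fit_predictive_model()] result on `rows`.
#' @param n_boot Number of bootstrap replicates (at least 199).
#' @param level Band level in (0, 1), e.g. 0.90.
#' @param alpha_grid Grid on which the band is evaluated; defaults to 50
#'   equispaced points over the data's alpha range.
#' @param seed Optional integer seed; a seeded call is exactly reproducible
#'   and leaves the caller's RNG state untouched.
#' @return Data frame with columns `alpha`, `lower`, `point`, `upper` and
#'   attributes `level`, `n_boot`, `band_type` (`"pairs percentile,
#'   pointwise"`), `n_failed` and `replicates` (the n_boot x n_grid matrix of
#'   replicate predictions, for diagnostics).
#' @export
bootstrap_band <- function(rows, model_kind, fit, n_boot = 999L,
                           level = 0.90, alpha_grid = NULL, seed = NULL) {
  stopifnot(inherits(fit, "lug_fit"))
  rows <- as.data.frame(rows)
  if (!fit$converged) {
    stop("point fit did not converge; refusing to bootstrap", call. = FALSE)
  }
  if (n_boot < 199L) stop("n_boot must be at least 199", call. = FALSE)
  .assert_prob(level, "level")
  if (is.null(alpha_grid)) {
    alpha_grid <- seq(min(rows$alpha), max(rows$alpha), length.out = 50L)
  }
  pred_fn <- if (model_kind == "street") predict_street_use else
    predict_daily_use
  start <- data.frame(beta2 = fit$params$beta2, beta3 = fit$params$beta3)
  n <- nrow(rows)

  reps <- .with_seed(seed, {
    t(vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      rb <- rows[idx, , drop = FALSE]
      if (diff(range(rb$alpha)) < 1e-10) return(rep(NA_real_, length(alpha_grid)))
      f <- .fit_once(rb$alpha, rb$observed_use, model_kind, start)
      if (f$convergence != 0L || !is.finite(f$beta1)) {
        return(rep(NA_real_, length(alpha_grid)))
      }
      pars <- empirical_params(f$beta1, f$beta2, f$beta3,
                               model_kind = model_kind)
      suppressWarnings(pred_fn(alpha_grid, pars))
    }, numeric(length(alpha_grid))))
  })

  failed <- apply(reps, 1L, function(r) anyNA(r))
  if (mean(failed) > 0.20) {
    stop(sprintf("bootstrap band unreliable: %.0f%% of replicates failed to refit",
                 100 * mean(failed)), call. = FALSE)
  }
  reps_ok <- reps[!failed, , drop = FALSE]
  lo <- (1 - level) / 2
  band <- data.frame(
    alpha = alpha_grid,
    lower = apply(reps_ok, 2L, quantile, probs = lo, names = FALSE),
    point = suppressWarnings(pred_fn(alpha_grid, fit$params)),
    upper = apply(reps_ok, 2L, quantile, probs = 1 - lo, names = FALSE)
  )
  structure(band, level = level, n_boot = n_boot,
            band_type = "pairs percentile, pointwise",
            n_failed = sum(failed), replicates = reps_ok)
}

# --- nonparametric specification check ---------------------------------------

# Local-linear smoother with Gaussian kernel: returns fitted values at `at`
# and, when requested, the hat diagonal at the data points (for LOO-CV).
.loclin <- function(x, y, at, h, hat_diag = FALSE) {
  fit <- numeric(length(at))
  hd <- if (hat_diag) numeric(length(at)) else NULL
  for (j in seq_along(at)) {
    d <- x - at[j]
    w <- exp(-0.5 * (d / h)^2)
    s0 <- sum(w); s1 <- sum(w * d); s2 <- sum(w * d^2)
    den <- s2 * s0 - s1^2
    if (den <= .Machine$double.eps * s2 * s0 || s0 == 0) {
      # near-singular (e.g. tiny h far from data): fall back to NW weights
      l <- w / max(s0, .Machine$double.xmin)
    } else {
      l <- w * (s2 - d * s1) / den
    }
    fit[j] <- sum(l * y)
    if (hat_diag) hd[j] <- l[which.min(abs(d))]
  }
  list(fit = fit, hat = hd)
}

.cv_bandwidth <- function(x, y, n_h = 21L) {
  n <- length(x)
  h_rot <- 1.06 * sd(x) * n^(-1 / 5)
  cand <- h_rot * 2^seq(-2.5, 2.5, length.out = n_h)
  score <- vapply(cand, function(h) {
    ll <- .loclin(x, y, x, h, hat_diag = TRUE)
    denom <- 1 - ll$hat
    if (any(denom <= 1e-8) || anyNA(ll$fit)) return(Inf)
    mean(((y - ll$fit) / denom)^2)
  }, numeric(1))
  if (all(!is.finite(score))) return(NA_real_)
  cand[which.min(score)]
}

#' Nonparametric specification check of a fitted use model
#'
#' Fits a local-linear kernel regression of observed use on the bilingual
#' proportion — with leave-one-out cross-validated bandwidth — and evaluates
#' it on the grid of a bootstrap band from [bootstrap_band()]. The share of
#' grid points where the nonparametric fit lies inside the band summarises
#' how compatible the data are with the parametric model: under a
#' well-specified model the share is high; systematic departures pull the
#' nonparametric curve out of the band.
#'
#' @param rows Locality table (columns `alpha`, `observed_use`).
#' @param band Band table from [bootstrap_band()].
#' @return An object of class `"lug_npcheck"`: list with `table` (columns
#'   `alpha`, `np_fit`, `lower`, `upper`, `inside`), `inside_share`,
#'   `bandwidth` and `bandwidth_method` (`"loo-cv"` or `"rule-of-thumb"`).
#' @export
nonparametric_check <- function(rows, band) {
  rows <- as.data.frame(rows)
  .check_rows(rows)
  stopifnot(all(c("alpha", "lower", "upper") %in% names(band)))
  x <- rows$alpha; y <- rows$observed_use
  h <- .cv_bandwidth(x, y)
  method <- "loo-cv"
  if (!is.finite(h)) {
    h <- tryCatch(KernSmooth::dpill(x, y), error = function(e) NA_real_)
    if (!is.finite(h) || h <= 0) h <- 1.06 * sd(x) * length(x)^(-1 / 5)
    method <- "rule-of-thumb"
    warning("cross-validated bandwidth selection failed; using rule-of-thumb bandwidth",
            call. = FALSE)
  }
  np_fit <- .loclin(x, y, band$alpha, h)$fit
  tab <- data.frame(alpha = band$alpha, np_fit = np_fit,
                    lower = band$lower, upper = band$upper,
                    inside = np_fit >= band$lower & np_fit <= band$upper)
  structure(list(table = tab, inside_share = mean(tab$inside),
                 bandwidth = h, bandwidth_method = method),
            class = "lug_npcheck")
}

#' @export
print.lug_npcheck <- function(x, ...) {
  cat(sprintf("Nonparametric specification check: %.0f%% of grid inside the band (bandwidth %.4g, %s)\n",
              100 * x$inside_share, x$bandwidth, x$bandwidth_method))
  invisible(x)
}
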