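#' Fit a probit survival curve to a seed storage experiment
#'
#' Seed death in storage is classically described by a straight line on
#' the probit scale: viability after `d` days is
#' \eqn{v = K_i - d/\sigma} probits, where \eqn{K_i} is the theoretical
#' initial viability and \eqn{\sigma} the days for viability to fall one
#' probit. `fit_probit()` estimates both by maximum-likelihood binomial
#' regression of germinated/sown on storage day with a probit link
#' (`Ki` is the intercept, `sigma = -1/slope`).
#'
#' With `include_nonresponders = TRUE` the observed proportion is modelled
#' as \eqn{(1-f)\,\Phi(K_i - d/\sigma)}: a fraction `f` of seeds can never
#' germinate and sits outside the ageing population, producing a plateau
#' below 100% at day 0. `f` is estimated by profiling the binomial
#' likelihood over a grid on `[0, 0.5]` followed by golden-section
#' refinement; the reported covariance of (intercept, slope) is the
#' profile covariance at the estimated `f`.
#'
#' Observations at 0% or 100% germination are retained — the binomial
#' likelihood handles them — but at least one observation strictly
#' between the extremes is required, otherwise the slope is
#' unidentifiable and the fit aborts with an explanatory error.
#'
#' @param data A tibble with columns `day`, `n_sown`, `n_germinated`
#'   (one row per packet; repeat days allowed), e.g. from
#'   [read_storage_experiments()] or [simulate_storage_experiment()].
#'   A `lot_id` column may be present but must contain a single lot.
#' @param include_nonresponders Estimate the never-germinating fraction
#'   `f` jointly? Default `FALSE` (`f = 0`).
#' @return An object of class `probit_fit` with elements `lot_id`, `Ki`
#'   (probits), `sigma` (days per probit), `slope`, `f`, `vcov` (2×2, for
#'   intercept and slope), `n_obs`, `deviance`, `logLik`, `converged`,
#'   and the fitting `data`. Supports [tidy()], [glance()], [autoplot()],
#'   [ki_interval()], [percentile_time()].
#' @examples
#' exp <- simulate_storage_experiment(Ki = 2, sigma = 5,
#'   days = seq(0, 20, 2.5), n_per_day = 100, seed = 1)
#' fit <- fit_probit(exp)
#' tidy(fit)
#' percentile_time(fit, 50)
#' @export
fit_probit <- function(data, include_nonresponders = FALSE) {
  lot_id <- if ("lot_id" %in% names(data)) unique(data$lot_id) else NA_character_
  if (length(lot_id) > 1) {
    abort("`data` contains several lots; fit one lot at a time (see `fit_probit_lots()`).")
  }
  if (!all(c("day", "n_sown", "n_germinated") %in% names(data))) {
    abort("`data` needs columns day, n_sown, n_germinated.")
  }
  check_counts(data$n_sown, data$n_germinated)
  if (any(data$day < 0)) abort("`day` must be non-negative.")
  if (length(unique(data$day)) < 2) {
    abort("Unidentifiable: need at least 2 distinct storage days.")
  }
  prop <- data$n_germinated / data$n_sown
  if (all(prop %in% c(0, 1))) {
    abort(paste0(
      "Unidentifiable: every observation is at 0% or 100% germination ",
      "(complete separation); the slope cannot be estimated."
    ))
  }

  if (!include_nonresponders) {
    fit <- quiet_glm(cbind(n_germinated, n_sown - n_germinated) ~ day,
                     family = binomial(link = "probit"), data = data,
                     control = stats::glm.control(epsilon = 1e-12, maxit = 100))
    if (!fit$converged) {
      # the deviance can oscillate at machine precision under a tight
      # epsilon; accept iff one further Newton step would barely move
      step <- tryCatch(drop(vcov(fit) %*% probit_score(data, coef(fit))),
                       error = function(e) Inf)
      if (max(abs(step)) > 1e-8) {
        abort(paste0("Probit fit did not converge in ", fit$iter,
                     " IWLS iterations."))
      }
    }
    a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
    out <- new_probit_fit(
      lot_id = lot_id, a = a, b = b, f = 0, vcov = unname(vcov(fit)),
      deviance = fit$deviance, logLik = as.numeric(stats::logLik(fit)),
      converged = TRUE, data = data,
      include_nonresponders = FALSE
    )
    return(out)
  }

  # non-responder model: profile the likelihood over f
  nll <- function(ab, f) {
    p <- (1 - f) * pnorm(ab[1] + ab[2] * data$day)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(dbinom(data$n_germinated, data$n_sown, p, log = TRUE))
  }
  start <- coef(quiet_glm(cbind(n_germinated, n_sown - n_germinated) ~ day,
                          family = binomial(link = "probit"), data = data))
  inner <- function(f) {
    stats::optim(start, function(ab) nll(ab, f), method = "BFGS",
                 control = list(maxit = 500))
  }
  grid <- seq(0, 0.5, by = 0.02)
  prof <- vapply(grid, function(f) inner(f)$value, numeric(1))
  f0 <- grid[which.min(prof)]
  lo <- max(0, f0 - 0.02); hi <- min(0.5, f0 + 0.02)
  ref <- optimize(function(f) inner(f)$value, c(lo, hi), tol = 1e-6)
  f_hat <- ref$minimum
  final <- stats::optim(inner(f_hat)$par, function(ab) nll(ab, f_hat),
                        method = "BFGS", hessian = TRUE,
                        control = list(maxit = 500))
  V <- tryCatch(solve(final$hessian), error = function(e) {
    warn("Profile Hessian is singular; covariance unavailable.")
    matrix(NA_real_, 2, 2)
  })
  new_probit_fit(
    lot_id = lot_id, a = final$par[1], b = final$par[2], f = f_hat,
    vcov = V, deviance = probit_deviance(data, final$par, f_hat),
    logLik = -final$value, converged = final$convergence == 0, data = data,
    include_nonresponders = TRUE
  )
}

# glm emits warnings for saturated 0/100% observations and for deviance
# oscillation under a tight epsilon; both are expected here (extreme
# observations are retained by design, convergence is re-checked via the
# score), so they are muffled rather than surfaced to the user.
quiet_glm <- function(...) {
  withCallingHandlers(
    glm(...),
    warning = function(w) {
      if (grepl("algorithm did not converge|fitted probabilities numerically",
                conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

# score (gradient of the binomial log-likelihood) of the probit line at ab
probit_score <- function(data, ab) {
  eta <- ab[1] + ab[2] * data$day
  mu <- pmin(pmax(pnorm(eta), 1e-12), 1 - 1e-12)
  resid <- (data$n_germinated - data$n_sown * mu) * dnorm(eta) / (mu * (1 - mu))
  c(sum(resid), sum(resid * data$day))
}

probit_deviance <- function(data, ab, f) {
  p <- pmin(pmax((1 - f) * pnorm(ab[1] + ab[2] * data$day), 1e-12), 1 - 1e-12)
  ll <- sum(dbinom(data$n_germinated, data$n_sown, p, log = TRUE))
  p_sat <- pmin(pmax(data$n_germinated / data$n_sown, 1e-12), 1 - 1e-12)
  ll_sat <- sum(dbinom(data$n_germinated, data$n_sown, p_sat, log = TRUE))
  2 * (ll_sat - ll)
}

new_probit_fit <- function(lot_id, a, b, f, vcov, deviance, logLik,
                           converged, data, include_nonresponders) {
  if (b >= 0) {
    warn("Fitted slope is non-negative: the lot shows no viability loss over the observed days; sigma is undefined.")
  }
  structure(
    list(
      lot_id = lot_id,
      Ki = unname(a),
      slope = unname(b),
      sigma = if (b < 0) -1 / unname(b) else NA_real_,
      f = f,
      vcov = vcov,
      n_obs = nrow(data),
      deviance = deviance,
      df_residual = nrow(data) - 2 - as.integer(include_nonresponders),
      logLik = logLik,
      converged = converged,
      include_nonresponders = include_nonresponders,
      data = tibble::as_tibble(data)
    ),
    class = "probit_fit"
  )
}

#' @export
print.probit_fit <- function(x, ...) {
  cat("Probit survival fit",
      if (!is.na(x$lot_id)) paste0(" (lot ", x$lot_id, ")"), "\n", sep = "")
  cat(sprintf("  Ki    = %.3f probits (%.3f%%)\n", x$Ki, probit_to_pct(x$Ki)))
  cat(sprintf("  sigma = %.3f days per probit\n", x$sigma))
  if (x$f > 0) cat(sprintf("  f     = %.3f non-responders\n", x$f))
  cat(sprintf("  %d observations, deviance %.2f on %d df\n",
              x$n_obs, x$deviance, x$df_residual))
  invisible(x)
}

#' @describeIn fit_probit Tidy coefficient table: one row each for `Ki`
#'   (probits), `sigma` (days), and `f` when estimated, with delta-method
#'   standard errors for `sigma`.
#' @param x,object A `probit_fit`.
#' @param ... Unused.
#' @method tidy probit_fit
#' @export
tidy.probit_fit <- function(x, ...) {
  se_a <- sqrt(x$vcov[1, 1])
  se_b <- sqrt(x$vcov[2, 2])
  se_sigma <- se_b / x$slope^2  # delta method on sigma = -1/b
  out <- tibble::tibble(
    term = c("Ki", "sigma"),
    estimate = c(x$Ki, x$sigma),
    std.error = c(se_a, se_sigma)
  )
  if (x$include_nonresponders) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      term = "f", estimate = x$f, std.error = NA_real_))
  }
  out
}

#' @describeIn fit_probit One-row model summary (`n_obs`, `deviance`,
#'   `df.residual`, `logLik`, `converged`).
#' @method glance probit_fit
#' @export
glance.probit_fit <- function(x, ...) {
  tibble::tibble(
    n_obs = x$n_obs, deviance = x$deviance, df.residual = x$df_residual,
    logLik = x$logLik, converged = x$converged, f = x$f
  )
}

#' @describeIn fit_probit Observed percentages and the fitted survival
#'   curve on one panel.
#' @method autoplot probit_fit
#' @export
autoplot.probit_fit <- function(object, ...) {
  obs <- object$data |>
    dplyr::mutate(pct = 100 * .data$n_germinated / .data$n_sown)
  grid <- tibble::tibble(day = seq(0, max(obs$day), length.out = 200))
  grid$pct <- 100 * (1 - object$f) * pnorm(object$Ki + object$slope * grid$day)
  ggplot2::ggplot(obs, ggplot2::aes(x = .data$day, y = .data$pct)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Storage (days)", y = "Germination (%)",
                  title = if (!is.na(object$lot_id)) object$lot_id) +
    ggplot2::ylim(0, 100)
}

#' Confidence interval for initial viability Ki
#'
#' Wald interval `Ki` ± z·SE(intercept) on the probit scale, with percent
#' equivalents. Because the whole survival curve informs the intercept,
#' this interval can be tighter than a single germination test of many
#' more seeds — the argument for storage experiments over large initial
#' tests when viability is very high.
#'
#' @param fit A `probit_fit`.
#' @param level Coverage, default 0.95.
#' @return A one-row tibble: `Ki`, `lower_probits`, `upper_probits`,
#'   `Ki_pct`, `lower_pct`, `upper_pct`, `level`.
#' @export
ki_interval <- function(fit, level = 0.95) {
  check_prob(level, "level")
  if (is.null(fit$vcov) || any(is.na(fit$vcov))) {
    abort("Fit has no covariance matrix; cannot form an interval.")
  }
  z <- qnorm(1 - (1 - level) / 2)
  se <- sqrt(fit$vcov[1, 1])
  lims <- fit$Ki + c(-1, 1) * z * se
  tibble::tibble(
    Ki = fit$Ki, lower_probits = lims[1], upper_probits = lims[2],
    Ki_pct = probit_to_pct(fit$Ki),
    lower_pct = probit_to_pct(lims[1]), upper_pct = probit_to_pct(lims[2]),
    level = level
  )
}

#' Time for viability to fall to a target percentage
#'
#' The storage time at which the fitted curve crosses `percentile_pct`
#' (e.g. 85 or 50, giving \eqn{p_{85}} and \eqn{p_{50}}):
#' \eqn{d = \sigma\,(K_i - \Phi^{-1}(q))} with `q` the target proportion
#' of the responding fraction. Confidence limits are by the delta method
#' on (intercept, slope) by default, or Fieller's theorem with
#' `method = "fieller"` (exact under joint normality of the
#' coefficients, and asymmetric near flat slopes).
#'
#' @param fit A `probit_fit`.
#' @param percentile_pct Target viability percent of seeds sown.
#' @param level Coverage for the limits, default 0.95.
#' @param method `"delta"` (default) or `"fieller"`.
#' @return A one-row tibble: `percentile_pct`, `days`, `lower_days`,
#'   `upper_days`, `level`, `method`.
#' @export
percentile_time <- function(fit, percentile_pct, level = 0.95,
                            method = c("delta", "fieller")) {
  method <- match.arg(method)
  check_prob(level, "level")
  if (percentile_pct <= 0 || percentile_pct >= 100) {
    abort("`percentile_pct` must be in (0, 100).")
  }
  q <- percentile_pct / 100 / (1 - fit$f)
  if (q >= pnorm(fit$Ki)) {
    abort(sprintf(
      "Percentile not reached: fitted initial viability is %.1f%%, below the %s%% target.",
      100 * (1 - fit$f) * pnorm(fit$Ki), format(percentile_pct)))
  }
  a <- fit$Ki; b <- fit$slope; V <- fit$vcov
  qn <- qnorm(q)
  days <- (qn - a) / b
  z <- qnorm(1 - (1 - level) / 2)
  if (method == "delta") {
    grad <- c(-1 / b, -(qn - a) / b^2)
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    lims <- days + c(-1, 1) * z * se
  } else {
    # Fieller: roots in d of (a + b d - qn)^2 = z^2 (v11 + 2 d v12 + d^2 v22)
    A <- b^2 - z^2 * V[2, 2]
    B <- 2 * (b * (a - qn) - z^2 * V[1, 2])
    C <- (a - qn)^2 - z^2 * V[1, 1]
    disc <- B^2 - 4 * A * C
    if (A <= 0 || disc < 0) {
      abort("Fieller interval is unbounded for this fit (slope not distinguishable from zero).")
    }
    lims <- sort((-B + c(-1, 1) * sqrt(disc)) / (2 * A))
  }
  tibble::tibble(
    percentile_pct = percentile_pct, days = days,
    lower_days = lims[1], upper_days = lims[2],
    level = level, method = method
  )
}

#' Fit probit survival curves for every lot in a table
#'
#' Convenience wrapper: splits a multi-lot storage-experiment tibble by
#' `lot_id` and fits each lot with [fit_probit()]. Lots that fail to fit
#' (e.g. no partial-germination observation) are kept with a recorded
#' error message rather than aborting the batch.
#'
#' @inheritParams fit_probit
#' @return A tibble with `lot_id`, a `fit` list-column (`probit_fit` or
#'   `NULL`), and `error` (message or `NA`).
#' @export
fit_probit_lots <- function(data, include_nonresponders = FALSE) {
  data |>
    dplyr::group_by(.data$lot_id) |>
    dplyr::group_map(function(d, key) {
      res <- tryCatch(
        list(fit = fit_probit(dplyr::mutate(d, lot_id = key$lot_id),
                              include_nonresponders), error = NA_character_),
        error = function(e) list(fit = NULL, error = conditionMessage(e))
      )
      tibble::tibble(lot_id = key$lot_id, fit = list(res$fit), error = res$error)
    }) |>
    dplyr::bind_rows()
}

#' Rank seed lots by time to reach a viability percentile
#'
#' Orders lots ascending by estimated time for viability to fall to
#' `percentile_pct` (shortest-lived first) — the basis for testing
#' genebank lots in longevity batches. Lots whose fitted initial
#' viability is already below the target cannot reach the percentile;
#' they rank first with `days = 0`. Ties break by `lot_id`.
#'
#' @param fits A list of `probit_fit` objects, or the tibble returned by
#'   [fit_probit_lots()] (rows with a fit error are dropped).
#' @param percentile_pct Target percent, default 85.
#' @return A tibble ordered by rank: `lot_id`, `days`, `attainable`,
#'   `rank`.
#' @export
rank_by_percentile <- function(fits, percentile_pct = 85) {
  if (is.data.frame(fits)) fits <- purrr::compact(fits$fit)
  if (length(fits) == 0) abort("No fits to rank.")
  rows <- purrr::map(fits, function(f) {
    attainable <- percentile_pct / 100 / (1 - f$f) < pnorm(f$Ki)
    days <- if (attainable) percentile_time(f, percentile_pct)$days else 0
    tibble::tibble(lot_id = f$lot_id, days = days, attainable = attainable)
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$days, .data$lot_id) |>
    dplyr::mutate(rank = dplyr::row_number())
}
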