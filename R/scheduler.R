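#' Define a viability monitoring policy
#'
#' Bundles the choices that drive monitoring schedules: the viability
#' standard (regeneration threshold), which interval rule to apply, and
#' how to react to results just above the standard.
#'
#' Interval rules:
#' * `"third_to_absolute_standard"` — one-third of the predicted time
#'   for viability to fall to the absolute standard (e.g. 85%).
#' * `"third_to_85pct_of_initial"` — one-third of the predicted time to
#'   reach 85% *of the initial viability*; with
#'   `nonresponder_aware = TRUE` the 85% is taken of the responding
#'   fraction only, which is the reading under which this rule makes
#'   sense when part of the population could never germinate.
#' * `"fixed"` — every `fixed_years` years (the 5-or-10-year fallback
#'   when no longevity prediction can be made).
#'
#' @param standard_pct Viability standard in percent, default 85.
#' @param interval_rule One of the rules above.
#' @param fixed_years Interval for the fixed rule (and the fallback when
#'   a prediction is unavailable), default 5.
#' @param nonresponder_aware Apply non-responder adjustments? Default
#'   `FALSE`.
#' @param warning_band_pct Width of the band above the standard in which
#'   a result triggers interval halving, default 2 (i.e. results of 86
#'   or 87% with an 85% standard).
#' @return An object of class `monitoring_policy`.
#' @export
monitoring_policy <- function(standard_pct = 85,
                              interval_rule = c("third_to_absolute_standard",
                                                "third_to_85pct_of_initial",
                                                "fixed"),
                              fixed_years = 5,
                              nonresponder_aware = FALSE,
                              warning_band_pct = 2) {
  interval_rule <- match.arg(interval_rule)
  if (standard_pct <= 0 || standard_pct >= 100) {
    abort("`standard_pct` must be in (0, 100).")
  }
  if (fixed_years <= 0) abort("`fixed_years` must be positive.")
  structure(
    list(standard_pct = standard_pct, interval_rule = interval_rule,
         fixed_years = fixed_years, nonresponder_aware = nonresponder_aware,
         warning_band_pct = warning_band_pct),
    class = "monitoring_policy"
  )
}

#' Set the initial monitoring interval for a lot
#'
#' Applies the policy's interval rule to a lot's survival-curve
#' parameters (from a storage-experiment fit or assumed species values).
#' A lot whose apparent initial viability is already at or below the
#' standard gets no interval but an immediate `"evaluate_now"` action;
#' a lot without a usable `sigma` falls back to the fixed rule.
#'
#' @param policy A [monitoring_policy()].
#' @param Ki Initial viability, probits (of the responding fraction).
#' @param sigma_days Days per probit; `NA` triggers the fixed fallback.
#' @param f Non-responder proportion, default 0.
#' @param lot_id Optional label carried into the plan.
#' @return A one-row plan tibble: `lot_id`, `next_test_day`,
#'   `interval_days`, `initial_interval_days`, `sigma_days`, `f`,
#'   `rationale`, `action` (`NA` or `"evaluate_now"`), `batch_rank`,
#'   `awaiting_batch`.
#' @examples
#' pol <- monitoring_policy()
#' initial_interval(pol, Ki = pct_to_probit(99),
#'                  sigma_days = 365.25 * 30 / (pct_to_probit(99) - pct_to_probit(85)))
#' @export
initial_interval <- function(policy, Ki, sigma_days, f = 0, lot_id = NA_character_) {
  stopifnot(inherits(policy, "monitoring_policy"))
  if (f < 0 || f >= 1) abort("`f` must be in [0, 1).")
  apparent_pct <- 100 * (1 - f) * pnorm(Ki)
  std <- policy$standard_pct
  if (apparent_pct <= std) {
    return(plan_row(lot_id, NA_real_, NA_real_, NA_real_, sigma_days, f,
                    sprintf("initial viability %.1f%% at or below standard %.0f%%",
                            apparent_pct, std),
                    action = "evaluate_now"))
  }
  rule <- policy$interval_rule
  if (rule != "fixed" && (is.na(sigma_days) || sigma_days <= 0)) {
    rule <- "fixed"  # no longevity prediction available
  }
  interval <- switch(
    rule,
    fixed = policy$fixed_years * DAYS_PER_YEAR,
    third_to_absolute_standard = {
      q <- if (policy$nonresponder_aware) std / 100 / (1 - f) else std / 100
      if (q >= pnorm(Ki)) {
        return(plan_row(lot_id, NA_real_, NA_real_, NA_real_, sigma_days, f,
                        "standard unreachable for responding fraction",
                        action = "evaluate_now"))
      }
      sigma_days * (Ki - qnorm(q)) / 3
    },
    third_to_85pct_of_initial = {
      if (policy$nonresponder_aware) {
        q <- 0.85 * pnorm(Ki)  # 85% of initial, within the responders
        sigma_days * (Ki - qnorm(q)) / 3
      } else {
        p_app <- apparent_pct / 100
        sigma_days * (qnorm(p_app) - qnorm(0.85 * p_app)) / 3
      }
    }
  )
  rationale <- sprintf(
    "%s: Ki = %.3f probits (%.1f%%), sigma = %s d, f = %.2f",
    rule, Ki, apparent_pct,
    if (is.na(sigma_days)) "NA" else sprintf("%.1f", sigma_days), f)
  plan_row(lot_id, interval, interval, interval, sigma_days, f, rationale)
}

plan_row <- function(lot_id, next_test_day, interval_days, initial_interval_days,
                     sigma_days, f, rationale, action = NA_character_,
                     batch_rank = NA_integer_, awaiting_batch = NA_integer_) {
  tibble::tibble(
    lot_id = lot_id, next_test_day = next_test_day,
    interval_days = interval_days,
    initial_interval_days = initial_interval_days,
    sigma_days = sigma_days, f = f, rationale = rationale,
    action = action, batch_rank = batch_rank, awaiting_batch = awaiting_batch
  )
}

#' Schedule ranked lots in longevity batches
#'
#' Partitions lots (ranked shortest-lived first by time to the
#' standard, see [rank_by_percentile()]) into `n_batches` of equal size
#' by longevity quantile. Batch 1 is scheduled immediately, at one-third
#' of each lot's predicted time to the standard; later batches carry an
#' `awaiting_batch` flag instead of a date — their testing starts only
#' when the previous batch's lots begin to reach the standard, which is
#' an event the genebank observes rather than predicts.
#'
#' @param rankings A tibble from [rank_by_percentile()] (`lot_id`,
#'   `days`, `attainable`, `rank`).
#' @param policy A [monitoring_policy()].
#' @param n_batches Number of longevity batches, default 2.
#' @return A plan tibble, one row per lot, with `batch_rank` set and
#'   `awaiting_batch = k - 1` for lots in batch `k > 1`. Lots whose
#'   percentile was unattainable get an `"evaluate_now"` action.
#' @export
batch_schedule <- function(rankings, policy, n_batches = 2) {
  stopifnot(inherits(policy, "monitoring_policy"))
  if (nrow(rankings) == 0) abort("`rankings` is empty.")
  n_batches <- min(n_batches, nrow(rankings))
  rankings |>
    dplyr::mutate(batch = dplyr::ntile(.data$rank, n_batches)) |>
    purrr::pmap(function(lot_id, days, attainable, rank, batch) {
      if (!attainable || days <= 0) {
        plan_row(lot_id, NA_real_, NA_real_, NA_real_, NA_real_, 0,
                 "percentile unattainable: initial viability at or below standard",
                 action = "evaluate_now", batch_rank = batch)
      } else {
        interval <- days / 3
        plan_row(
          lot_id,
          next_test_day = if (batch == 1) interval else NA_real_,
          interval_days = interval, initial_interval_days = interval,
          sigma_days = NA_real_, f = 0,
          rationale = sprintf("batch %d: one-third of %.1f d to standard",
                              batch, days),
          batch_rank = batch,
          awaiting_batch = if (batch > 1) batch - 1L else NA_integer_
        )
      }
    }) |>
    dplyr::bind_rows()
}

#' Revise a monitoring plan after a test result
#'
#' Implements the schedule-revision step: an out-of-tolerance replicated
#' test is not trusted (`"retest"`, schedule unchanged); a pooled result
#' at or below the standard triggers `"regenerate"`; a result inside the
#' warning band just above the standard halves the interval (detecting
#' decline early without re-predicting after every test); anything
#' higher keeps the current interval, recomputing it from the lot's
#' `sigma` when available but never lengthening it — intervals only
#' ratchet down over a lot's lifetime.
#'
#' @param plan A one-row plan tibble (from [initial_interval()] or a
#'   previous update).
#' @param test A tibble of replicate counts (`n_sown`, `n_germinated`)
#'   for the test just performed.
#' @param policy A [monitoring_policy()].
#' @param tolerance_alpha Significance level for the replicate tolerance
#'   check, default 0.05.
#' @return The revised one-row plan tibble; `action` is `NA`,
#'   `"retest"`, or `"regenerate"`.
#' @export
update_after_result <- function(plan, test, policy, tolerance_alpha = 0.05) {
  stopifnot(inherits(policy, "monitoring_policy"), nrow(plan) == 1)
  check_counts(test$n_sown, test$n_germinated)
  if (nrow(test) > 1) {
    tol <- tolerance_test(test, alpha = tolerance_alpha)
    if (!tol$in_tolerance) {
      plan$action <- "retest"
      plan$rationale <- sprintf(
        "replicates out of tolerance (range %d > %d); schedule unchanged",
        tol$observed_range, tol$tolerated_range)
      return(plan)
    }
  }
  pct <- 100 * sum(test$n_germinated) / sum(test$n_sown)
  std <- policy$standard_pct
  if (pct <= std) {
    plan$action <- "regenerate"
    plan$rationale <- sprintf("result %.1f%% at or below standard %.0f%%", pct, std)
    plan$next_test_day <- NA_real_
    return(plan)
  }
  if (pct <= std + policy$warning_band_pct) {
    new_interval <- plan$interval_days / 2
    rationale <- sprintf("result %.1f%% in warning band (%.0f-%.0f%%): interval halved",
                         pct, std + 1, std + policy$warning_band_pct)
  } else {
    recomputed <- if (!is.na(plan$sigma_days) && plan$sigma_days > 0 && pct < 100) {
      plan$sigma_days * (pct_to_probit(pct) - pct_to_probit(std)) / 3
    } else {
      plan$interval_days
    }
    new_interval <- min(recomputed, plan$interval_days, plan$initial_interval_days)
    rationale <- sprintf("result %.1f%%: interval %.1f d (capped at current/initial)",
                         pct, new_interval)
  }
  plan$interval_days <- new_interval
  base_day <- if (is.na(plan$next_test_day)) 0 else plan$next_test_day
  plan$next_test_day <- base_day + new_interval
  plan$rationale <- rationale
  plan$action <- NA_character_
  plan
}
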