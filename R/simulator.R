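#' Simulate one germination test from a known survival curve
#'
#' Draws replicate counts around the true survival curve: each replicate
#' is \eqn{\mathrm{Binomial}(n, (1-f)\,\Phi(K_i - d/\sigma))}. An
#' optional overdispersion parameter draws each replicate's probability
#' from a Beta distribution with that intra-class correlation, emulating
#' scorer bias or micro-environment heterogeneity that makes real
#' replicates more variable than binomial.
#'
#' @param Ki True initial viability, probits.
#' @param sigma True days per probit.
#' @param day Storage day of the test.
#' @param n_sown Seeds per replicate, default 50.
#' @param replicates Number of replicates, default 2.
#' @param f True non-responder proportion, default 0.
#' @param overdispersion Intra-class correlation rho in `[0, 1)`,
#'   default 0 (pure binomial).
#' @param seed Optional seed; when given the draw happens in a local RNG
#'   scope, when `NULL` the current stream is used.
#' @param lot_id,test_date,test_kind Metadata for the returned records.
#' @return A germination-test tibble (canonical columns, one row per
#'   replicate) compatible with [write_germination_tests()].
#' @examples
#' simulate_test(Ki = 2, sigma = 1000, day = 0, seed = 1)
#' @export
simulate_test <- function(Ki, sigma, day, n_sown = 50, replicates = 2, f = 0,
                          overdispersion = 0, seed = NULL, lot_id = "sim",
                          test_date = as.Date("2000-01-01") + day,
                          test_kind = "monitoring") {
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (f < 0 || f >= 1) abort("`f` must be in [0, 1).")
  if (overdispersion < 0 || overdispersion >= 1) {
    abort("`overdispersion` must be in [0, 1).")
  }
  p <- (1 - f) * pnorm(Ki - day / sigma)
  draw <- function() {
    if (overdispersion > 0 && p > 0 && p < 1) {
      prec <- (1 - overdispersion) / overdispersion
      pr <- stats::rbeta(replicates, p * prec, (1 - p) * prec)
      rbinom(replicates, n_sown, pr)
    } else {
      rbinom(replicates, n_sown, p)
    }
  }
  x <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  tibble::tibble(
    lot_id = lot_id, test_date = test_date,
    replicate = seq_len(replicates),
    n_sown = as.integer(n_sown), n_germinated = as.integer(x),
    pretreatment = NA_character_, test_kind = test_kind
  )
}

#' Simulate a seed storage experiment
#'
#' One packet of `n_per_day` seeds per entry of `days`, drawn from the
#' true survival curve — the fixture generator for probit
#' parameter-recovery and reduced-design studies (e.g. comparing a full
#' 10-point design with a 4-point screen).
#'
#' @inheritParams simulate_test
#' @param days Sampling grid, non-negative (repeats allowed —
#'   independent packets).
#' @param n_per_day Seeds sown per packet; scalar or one per day.
#' @param moisture_pct,temperature_c Recorded storage conditions.
#' @return A storage-experiment tibble (`lot_id`, `day`, `n_sown`,
#'   `n_germinated`, `moisture_pct`, `temperature_c`).
#' @export
simulate_storage_experiment <- function(Ki, sigma, days, n_per_day = 100,
                                        f = 0, seed = NULL, lot_id = "sim",
                                        moisture_pct = NA_real_,
                                        temperature_c = NA_real_) {
  if (length(days) == 0) abort("`days` must be non-empty.")
  if (sigma <= 0) abort("`sigma` must be positive.")
  n_per_day <- rep_len(n_per_day, length(days))
  draw <- function() {
    p <- (1 - f) * pnorm(Ki - days / sigma)
    rbinom(length(days), n_per_day, p)
  }
  x <- if (is.null(seed)) draw() else with_local_seed(seed, draw())
  tibble::tibble(
    lot_id = lot_id, day = days, n_sown = as.integer(n_per_day),
    n_germinated = as.integer(x),
    moisture_pct = moisture_pct, temperature_c = temperature_c
  ) |>
    dplyr::arrange(.data$day)
}

#' Simulate a cohort of seed lots with known ground truth
#'
#' Draws per-lot true parameters: `Ki` normal on the probit scale,
#' `sigma` log-normal (keeping it positive and right-skewed, matching
#' the large between-lot longevity variation seen within a species), and
#' a non-responder fraction that is zero for most lots with an optional
#' contaminated share. The defaults describe a genebank-storage cohort
#' in which roughly one lot in ten reaches an 85% standard within a
#' 20-year horizon, so scheduling policies face a non-trivial mix of
#' short- and long-lived lots.
#'
#' @param n_lots Number of lots.
#' @param Ki_mean,Ki_sd Probit-scale normal parameters for true `Ki`.
#' @param sigma_meanlog,sigma_sdlog Log-scale parameters for true
#'   `sigma` in days (defaults centre on ~27 years per probit).
#' @param f_prob Probability a lot carries non-responders, default 0.
#' @param f_value Non-responder fraction for such lots, default 0.1.
#' @param seed RNG seed (local scope), default 1.
#' @return A truth tibble: `lot_id`, `Ki_true`, `sigma_true`, `f_true`.
#' @export
simulate_cohort <- function(n_lots, Ki_mean = 2.5, Ki_sd = 0.4,
                            sigma_meanlog = log(10000), sigma_sdlog = 0.6,
                            f_prob = 0, f_value = 0.1, seed = 1) {
  if (n_lots < 1) abort("`n_lots` must be at least 1.")
  if (Ki_sd <= 0 || sigma_sdlog <= 0) abort("Scale parameters must be positive.")
  with_local_seed(seed, tibble::tibble(
    lot_id = sprintf("LOT%04d", seq_len(n_lots)),
    Ki_true = rnorm(n_lots, Ki_mean, Ki_sd),
    sigma_true = rlnorm(n_lots, sigma_meanlog, sigma_sdlog),
    f_true = ifelse(runif(n_lots) < f_prob, f_value, 0)
  ))
}

#' Simulate decades of monitoring under a policy
#'
#' Event-driven simulation of a cohort in storage: each lot gets an
#' initial test at day 0, an interval from [initial_interval()] (using
#' the initial result as the `Ki` estimate and the true `sigma` as the
#' longevity prediction, as when species constants are known), and then
#' repeated monitoring tests with [update_after_result()] until
#' regeneration is flagged or the horizon ends. The log records, for
#' every test, the observed pooled percentage next to the true
#' viability, so detection delays and below-standard-at-test rates can
#' be measured exactly.
#'
#' @param truth A cohort truth tibble from [simulate_cohort()].
#' @param policy A [monitoring_policy()].
#' @param horizon_years Length of the simulated period.
#' @param n_sown,replicates Test design, defaults 50 seeds × 2.
#' @param seed RNG seed (local scope), default 1.
#' @return A list with `tests` (germination-test rows across all lots)
#'   and `events` (one row per test: `lot_id`, `day`, `observed_pct`,
#'   `true_pct`, `action`, `interval_days`, `seeds_used`).
#' @export
simulate_history <- function(truth, policy, horizon_years, n_sown = 50,
                             replicates = 2, seed = 1) {
  stopifnot(inherits(policy, "monitoring_policy"))
  horizon_days <- horizon_years * DAYS_PER_YEAR
  with_local_seed(seed, {
    out <- purrr::pmap(truth, function(lot_id, Ki_true, sigma_true, f_true, ...) {
      tests <- list(); events <- list()
      run_test <- function(day, kind) {
        simulate_test(Ki_true, sigma_true, day, n_sown = n_sown,
                      replicates = replicates, f = f_true, lot_id = lot_id,
                      test_kind = kind)
      }
      t0 <- run_test(0, "initial")
      pct0 <- 100 * sum(t0$n_germinated) / sum(t0$n_sown)
      Ki_est <- pct_to_probit(min(max(pct0, 0.5), 99.9))
      plan <- initial_interval(policy, Ki_est, sigma_true, f = 0,
                               lot_id = lot_id)
      tests[[1]] <- t0
      events[[1]] <- tibble::tibble(
        lot_id = lot_id, day = 0, observed_pct = pct0,
        true_pct = 100 * (1 - f_true) * pnorm(Ki_true),
        action = plan$action, interval_days = plan$interval_days,
        seeds_used = sum(t0$n_sown)
      )
      if (horizon_years > 0 && is.na(plan$action)) {
        while (!is.na(plan$next_test_day) && plan$next_test_day <= horizon_days) {
          day <- plan$next_test_day
          tst <- run_test(day, "monitoring")
          plan <- update_after_result(plan, tst, policy)
          tests[[length(tests) + 1]] <- tst
          events[[length(events) + 1]] <- tibble::tibble(
            lot_id = lot_id, day = day,
            observed_pct = 100 * sum(tst$n_germinated) / sum(tst$n_sown),
            true_pct = 100 * (1 - f_true) * pnorm(Ki_true - day / sigma_true),
            action = plan$action, interval_days = plan$interval_days,
            seeds_used = sum(tst$n_sown)
          )
          if (!is.na(plan$action) && plan$action == "regenerate") break
        }
      }
      list(tests = dplyr::bind_rows(tests), events = dplyr::bind_rows(events))
    })
    list(
      tests = dplyr::bind_rows(purrr::map(out, "tests")),
      events = dplyr::bind_rows(purrr::map(out, "events"))
    )
  })
}
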