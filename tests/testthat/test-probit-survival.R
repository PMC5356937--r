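test_that("noiseless data invert to the generating Ki and sigma", {
  days <- seq(0, 30, by = 3)
  n <- 1e6
  dat <- tibble::tibble(
    day = days, n_sown = n,
    n_germinated = round(n * pnorm(2 - days / 5))
  )
  fit <- fit_probit(dat)
  expect_equal(fit$Ki, 2, tolerance = 1e-2)
  expect_equal(fit$sigma, 5, tolerance = 1e-2)
})

test_that("probit fit equals an independent IRLS oracle on random data", {
  set.seed(7)
  for (i in 1:20) {
    days <- sort(sample(0:30, 6))
    Ki <- runif(1, 1, 3); sigma <- runif(1, 3, 15)
    n <- sample(c(25, 50, 100), 1)
    x <- rbinom(length(days), n, pnorm(Ki - days / sigma))
    if (all(x %in% c(0, n))) next
    dat <- tibble::tibble(day = days, n_sown = n, n_germinated = x)
    fit <- fit_probit(dat)
    oracle <- irls_probit(days, rep(n, length(days)), x)
    expect_equal(unname(c(fit$Ki, fit$slope)), unname(oracle),
                 tolerance = 1e-6)
  }
})

test_that("unidentifiable or malformed experiments abort with clear errors", {
  flat <- tibble::tibble(day = c(0, 10), n_sown = 50, n_germinated = c(50, 50))
  expect_error(fit_probit(flat), "Unidentifiable")
  dead <- tibble::tibble(day = c(0, 10), n_sown = 50, n_germinated = c(0, 0))
  expect_error(fit_probit(dead), "Unidentifiable")
  one_day <- tibble::tibble(day = c(5, 5), n_sown = 50, n_germinated = c(40, 30))
  expect_error(fit_probit(one_day), "distinct storage days")
})

test_that("ki_interval applies the Wald construction and percent mapping", {
  exp <- simulate_storage_experiment(Ki = 2.5, sigma = 6, days = seq(0, 27, 3),
                                     n_per_day = 100, seed = 11)
  fit <- fit_probit(exp)
  ki <- ki_interval(fit, level = 0.95)
  z <- qnorm(0.975)
  se <- sqrt(fit$vcov[1, 1])
  expect_equal(ki$lower_probits, fit$Ki - z * se)
  expect_equal(ki$upper_probits, fit$Ki + z * se)
  expect_equal(ki$lower_pct, probit_to_pct(fit$Ki - z * se))
  # degenerate SE collapses the interval to the point estimate
  degen <- fit
  degen$vcov <- matrix(0, 2, 2)
  kid <- ki_interval(degen)
  expect_equal(kid$lower_probits, kid$upper_probits)
  expect_equal(kid$lower_probits, fit$Ki)
})

test_that("percentile times follow the closed form and its ordering", {
  exp <- simulate_storage_experiment(Ki = 2, sigma = 5, days = seq(0, 20, 2),
                                     n_per_day = 200, seed = 3)
  fit <- fit_probit(exp)
  p50 <- percentile_time(fit, 50)
  expect_equal(p50$days, fit$sigma * fit$Ki, tolerance = 1e-10)
  p85 <- percentile_time(fit, 85)
  expect_equal(p85$days, fit$sigma * (fit$Ki - qnorm(0.85)), tolerance = 1e-10)
  expect_lt(p85$days, p50$days)
  expect_true(p50$lower_days <= p50$days && p50$days <= p50$upper_days)
  # exact closed-form case: Ki = 2, sigma = 5
  expect_equal(5 * (2 - qnorm(0.85)), 4.818, tolerance = 5e-4)
  # Fieller limits agree with delta to first order on a well-determined fit
  fieller <- percentile_time(fit, 50, method = "fieller")
  expect_equal(fieller$lower_days, p50$lower_days, tolerance = 0.05)
  expect_error(percentile_time(fit, 99.99), "not reached")
})

test_that("percentile time increases in Ki and sigma", {
  base <- expand.grid(Ki = c(1.5, 2, 2.5, 3), sigma = c(4, 8, 16))
  days <- with(base, sigma * (Ki - qnorm(0.85)))
  by_ki <- matrix(days, nrow = 4)
  expect_true(all(apply(by_ki, 2, diff) > 0))  # in Ki at fixed sigma
  expect_true(all(apply(by_ki, 1, diff) > 0))  # in sigma at fixed Ki
})

test_that("non-responder fraction is recovered from a plateaued experiment", {
  exp <- simulate_storage_experiment(
    Ki = 3, sigma = 8, f = 0.10, days = seq(0, 40, 4), n_per_day = 200,
    seed = 19
  )
  fit <- fit_probit(exp, include_nonresponders = TRUE)
  expect_lt(abs(fit$f - 0.10), 0.05)
  expect_lt(abs(fit$Ki - 3), 0.5)
  expect_lt(abs(fit$sigma - 8), 1)
  # fitted curve plateaus near 90% at day 0
  expect_equal(100 * (1 - fit$f) * pnorm(fit$Ki), 90, tolerance = 3)
})

test_that("Wald intervals for Ki and sigma tighten as packets grow", {
  ses <- purrr::map_dbl(c(25, 50, 100, 200), function(n) {
    exp <- simulate_storage_experiment(Ki = 2.98, sigma = 6,
                                       days = seq(0, 27, 3), n_per_day = n,
                                       seed = 100 + n)
    fit <- fit_probit(exp)
    tidy(fit)$std.error[tidy(fit)$term == "sigma"]
  })
  expect_true(all(diff(ses) < 0))
})

test_that("reduced four-point designs stay inside the full fit's p50 interval", {
  set.seed(23)
  inside <- purrr::map_lgl(1:50, function(i) {
    full_days <- seq(0, 27, 3)
    exp <- simulate_storage_experiment(Ki = 2.5, sigma = 6, days = full_days,
                                       n_per_day = 50)
    full <- fit_probit(exp)
    ci <- percentile_time(full, 50)
    reduced <- exp[exp$day %in% full_days[c(2, 4, 6, 8)], ]
    p50_red <- tryCatch(percentile_time(fit_probit(reduced), 50)$days,
                        error = function(e) NA_real_)
    !is.na(p50_red) && ci$lower_days <= p50_red && p50_red <= ci$upper_days
  })
  expect_gte(mean(inside, na.rm = TRUE), 0.7)
})

test_that("lots rank ascending by percentile time with deterministic ties", {
  mk <- function(lot, Ki, sigma, seed) {
    fit_probit(simulate_storage_experiment(Ki = Ki, sigma = sigma,
                                           days = seq(0, 30, 3),
                                           n_per_day = 400, seed = seed,
                                           lot_id = lot))
  }
  fits <- list(mk("C", 2, 8, 1), mk("A", 2, 3, 2), mk("B", 2, 5.5, 3))
  rk <- rank_by_percentile(fits, 85)
  expect_equal(rk$lot_id, c("A", "B", "C"))
  expect_true(all(diff(rk$days) > 0))

  # a lot already below the target ranks first with zero days
  low <- mk("Z", pct_to_probit(70), 5, 4)
  rk2 <- rank_by_percentile(list(fits[[1]], low), 85)
  expect_equal(rk2$lot_id[1], "Z")
  expect_equal(rk2$days[1], 0)
  expect_false(rk2$attainable[1])
})

test_that("tidy and glance expose coefficients and fit diagnostics", {
  exp <- simulate_storage_experiment(Ki = 2, sigma = 5, days = seq(0, 20, 2),
                                     n_per_day = 100, seed = 5)
  fit <- fit_probit(exp)
  td <- tidy(fit)
  expect_equal(td$term, c("Ki", "sigma"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$n_obs, nrow(exp))
  expect_true(gl$converged)
  expect_s3_class(autoplot(fit), "ggplot")
})
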