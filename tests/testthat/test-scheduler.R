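years <- function(d) d / 365.25
days <- function(y) y * 365.25

test_that("the one-third rule turns a 30-year prediction into a 10-year interval", {
  pol <- monitoring_policy(interval_rule = "third_to_absolute_standard")
  Ki <- pct_to_probit(99)
  sigma <- days(30) / (Ki - pct_to_probit(85))  # time to 85% is 30 y
  plan <- initial_interval(pol, Ki, sigma)
  expect_equal(years(plan$interval_days), 10, tolerance = 1e-10)
  expect_true(is.na(plan$action))
})

test_that("lots at or below the standard get an immediate action, not an interval", {
  pol <- monitoring_policy()
  plan <- initial_interval(pol, pct_to_probit(80), sigma_days = 1000)
  expect_equal(plan$action, "evaluate_now")
  expect_true(is.na(plan$interval_days))
})

test_that("a missing longevity prediction falls back to the fixed rule", {
  pol <- monitoring_policy(fixed_years = 5)
  plan <- initial_interval(pol, pct_to_probit(95), sigma_days = NA)
  expect_equal(plan$interval_days, days(5))
  pol10 <- monitoring_policy(interval_rule = "fixed", fixed_years = 10)
  plan10 <- initial_interval(pol10, pct_to_probit(95), sigma_days = 2000)
  expect_equal(plan10$interval_days, days(10))
})

test_that("non-responder awareness lengthens the 85%-of-initial interval", {
  # two lots with the same ~90% apparent initial viability: one truly at
  # 90%, one at ~100% of responders with f = 0.10
  sigma <- 2000
  pol_plain <- monitoring_policy(interval_rule = "third_to_85pct_of_initial")
  pol_aware <- monitoring_policy(interval_rule = "third_to_85pct_of_initial",
                                 nonresponder_aware = TRUE)
  plain <- initial_interval(pol_plain, pct_to_probit(90), sigma, f = 0)
  aware <- initial_interval(pol_aware, 3.5, sigma, f = 0.10)
  expect_equal(100 * 0.9 * pnorm(3.5), 90, tolerance = 0.1)  # same apparent %
  expect_gt(aware$interval_days, plain$interval_days)
  # closed forms behind both intervals
  expect_equal(plain$interval_days,
               sigma * (pct_to_probit(90) - qnorm(0.85 * 0.9)) / 3)
  expect_equal(aware$interval_days,
               sigma * (3.5 - qnorm(0.85 * pnorm(3.5))) / 3)
})

test_that("batch scheduling splits ranked lots into longevity quantiles", {
  pol <- monitoring_policy()
  rk <- tibble::tibble(
    lot_id = c("a", "b", "c", "d"),
    days = days(c(2, 4, 6, 8)),
    attainable = TRUE, rank = 1:4
  )
  plans <- batch_schedule(rk, pol, n_batches = 2)
  expect_equal(plans$batch_rank, c(1L, 1L, 2L, 2L))
  # batch 1 is dated; batch 2 waits on an event flag
  expect_true(all(!is.na(plans$next_test_day[1:2])))
  expect_true(all(is.na(plans$next_test_day[3:4])))
  expect_equal(plans$awaiting_batch, c(NA, NA, 1L, 1L))
  expect_equal(plans$interval_days, rk$days / 3)

  # a single lot forms a single dated batch
  single <- batch_schedule(rk[1, ], pol, n_batches = 4)
  expect_equal(single$batch_rank, 1L)
  expect_equal(single$next_test_day, rk$days[1] / 3)
})

test_that("results drive regeneration, warning-band halving, and capping", {
  pol <- monitoring_policy()
  plan <- initial_interval(pol, pct_to_probit(95), sigma_days = 2000,
                           lot_id = "L")
  test_at <- function(pct) tibble::tibble(n_sown = 100L,
                                          n_germinated = as.integer(pct))
  expect_equal(update_after_result(plan, test_at(84), pol)$action, "regenerate")
  expect_equal(update_after_result(plan, test_at(85), pol)$action, "regenerate")
  halved <- update_after_result(plan, test_at(86), pol)
  expect_equal(halved$interval_days, plan$interval_days / 2)
  high <- update_after_result(plan, test_at(95), pol)
  expect_lte(high$interval_days, plan$initial_interval_days)
  expect_true(is.na(high$action))
})

test_that("out-of-tolerance replicates trigger a retest, schedule unchanged", {
  pol <- monitoring_policy()
  plan <- initial_interval(pol, pct_to_probit(95), sigma_days = 2000)
  discordant <- tibble::tibble(n_sown = c(100L, 100L),
                               n_germinated = c(95L, 60L))
  upd <- update_after_result(plan, discordant, pol)
  expect_equal(upd$action, "retest")
  expect_equal(upd$interval_days, plan$interval_days)
  expect_equal(upd$next_test_day, plan$next_test_day)
})

test_that("intervals never lengthen over a lot's lifetime", {
  pol <- monitoring_policy()
  plan <- initial_interval(pol, pct_to_probit(97), sigma_days = 3000,
                           lot_id = "L")
  results <- c(96, 98, 93, 90, 87, 86)
  intervals <- plan$interval_days
  for (pct in results) {
    plan <- update_after_result(
      plan, tibble::tibble(n_sown = 100L, n_germinated = as.integer(pct)), pol)
    intervals <- c(intervals, plan$interval_days)
  }
  expect_true(all(diff(intervals) <= 1e-9))
  expect_true(all(intervals > 0))
})

test_that("the one-third interval grows with Ki and sigma", {
  pol <- monitoring_policy(interval_rule = "third_to_absolute_standard")
  iv <- function(Ki, sigma) initial_interval(pol, Ki, sigma)$interval_days
  expect_lt(iv(pct_to_probit(92), 2000), iv(pct_to_probit(97), 2000))
  expect_lt(iv(pct_to_probit(95), 1500), iv(pct_to_probit(95), 3000))
})
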