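test_that("reading groups replicates into tests with pooled percentages", {
  path <- write_temp_csv(c(
    "lot_id,test_date,replicate,n_sown,n_germinated,pretreatment,test_kind",
    "L1,2010-05-01,1,100,98,none,initial",
    "L1,2010-05-01,2,100,96,none,initial"
  ))
  tests <- read_germination_tests(path)
  expect_equal(nrow(tests), 2)
  pooled <- summarise_tests(tests)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$pct, 97.0)
})

test_that("invalid rows are rejected with their row number", {
  path <- write_temp_csv(c(
    "lot_id,test_date,replicate,n_sown,n_germinated,pretreatment,test_kind",
    "L1,2010-05-01,1,100,105,none,initial",
    "L1,2010-05-01,2,100,96,none,initial",
    "L2,2010-06-01,1,50,-3,none,monitoring"
  ))
  expect_warning(tests <- read_germination_tests(path), "rejected")
  probs <- attr(tests, "problems")
  expect_setequal(probs$row, c(1, 3))
  expect_match(probs$message[probs$row == 1], "exceeds n_sown")
  expect_equal(nrow(tests), 1)
})

test_that("empty files give empty tibbles, and schema remapping works", {
  empty <- write_temp_csv("lot_id,test_date,replicate,n_sown,n_germinated,pretreatment,test_kind")
  expect_equal(nrow(read_germination_tests(empty)), 0)

  renamed <- write_temp_csv(c(
    "accession,when,rep,sown,germ",
    "L1,2010-05-01,1,100,98"
  ))
  tests <- read_germination_tests(renamed, schema = c(
    lot_id = "accession", test_date = "when", replicate = "rep",
    n_sown = "sown", n_germinated = "germ"
  ))
  expect_equal(tests$n_germinated, 98L)
  expect_error(read_germination_tests(renamed, schema = c(bogus = "x")),
               "Unknown schema")
})

test_that("germination and storage CSVs round-trip through write/read", {
  tests <- dplyr::bind_rows(
    simulate_test(Ki = 2, sigma = 2000, day = 0, seed = 1, lot_id = "A",
                  test_kind = "initial"),
    simulate_test(Ki = 2, sigma = 2000, day = 1900, seed = 2, lot_id = "A"),
    simulate_test(Ki = 2.5, sigma = 900, day = 500, seed = 3, lot_id = "B")
  )
  path <- tempfile(fileext = ".csv")
  write_germination_tests(tests, path)
  back <- read_germination_tests(path)
  attr(back, "problems") <- NULL  # empty diagnostics, not data
  expect_equal(as.data.frame(back), as.data.frame(tests))

  exp <- simulate_storage_experiment(Ki = 2, sigma = 5, days = seq(0, 15, 3),
                                     seed = 4, moisture_pct = 10.9,
                                     temperature_c = 45)
  path2 <- tempfile(fileext = ".csv")
  write_storage_experiments(exp, path2)
  expect_equal(as.data.frame(read_storage_experiments(path2)),
               as.data.frame(exp))
})

test_that("transition summary reproduces hand-counted pairs", {
  mk <- function(lot, date, x) tibble::tibble(
    lot_id = lot, test_date = as.Date(date), replicate = 1L,
    n_sown = 100L, n_germinated = as.integer(x),
    pretreatment = NA_character_, test_kind = "monitoring"
  )
  tests <- dplyr::bind_rows(
    mk("A", "2000-01-01", 90), mk("A", "2005-01-01", 80),
    mk("B", "2000-01-01", 90), mk("B", "2005-01-01", 95)
  )
  out <- transition_summary(tests, threshold_pct = 85, lag_years = c(4, 6))
  expect_equal(out$original_pct, 90)
  expect_equal(out$prop_le_threshold, 0.5)
  expect_equal(out$prop_ge_threshold_plus1, 0.5)
  expect_equal(out$prop_ge_original, 0.5)

  single <- dplyr::bind_rows(mk("C", "2000-01-01", 86), mk("C", "2005-06-01", 86))
  out2 <- transition_summary(single)
  expect_equal(out2$prop_le_threshold, 0)
  expect_equal(out2$prop_ge_threshold_plus1, 1)
  expect_equal(out2$prop_ge_original, 1)

  # out-of-window lags yield no rows, not an error
  near <- dplyr::bind_rows(mk("D", "2000-01-01", 90), mk("D", "2001-01-01", 80))
  expect_equal(nrow(transition_summary(near)), 0)
})

test_that("transition proportions match direct enumeration on a cohort", {
  set.seed(42)
  tests <- purrr::map(1:300, function(i) {
    lot <- sprintf("L%03d", i)
    dplyr::bind_rows(
      simulate_test(Ki = 1.8, sigma = 4000, day = 0, n_sown = 100,
                    replicates = 1, lot_id = lot,
                    test_date = as.Date("2000-01-01")),
      simulate_test(Ki = 1.8, sigma = 4000, day = 1827, n_sown = 100,
                    replicates = 1, lot_id = lot,
                    test_date = as.Date("2005-01-01"))
    )
  }) |>
    dplyr::bind_rows()
  out <- transition_summary(tests, threshold_pct = 85, lag_years = c(4, 6))

  # direct enumeration over the generated pairs, coded independently
  wide <- tests |>
    dplyr::mutate(when = ifelse(test_date == as.Date("2000-01-01"), "orig", "next")) |>
    dplyr::select(lot_id, when, n_germinated) |>
    tidyr::pivot_wider(names_from = when, values_from = n_germinated)
  for (v in out$original_pct) {
    sel <- wide[wide$orig == v, ]
    expect_equal(out$prop_le_threshold[out$original_pct == v],
                 mean(sel[["next"]] <= 85))
    expect_equal(out$prop_ge_original[out$original_pct == v],
                 mean(sel[["next"]] >= sel$orig))
  }
  # the first two categories partition every row
  expect_equal(out$prop_le_threshold + out$prop_ge_threshold_plus1,
               rep(1, nrow(out)))
})
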