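#' Read germination test records from CSV
#'
#' Reads a monitoring-test table with one row per replicate and validates
#' the counts. The canonical columns are `lot_id`, `test_date` (ISO-8601),
#' `replicate`, `n_sown`, `n_germinated`, `pretreatment`, `test_kind`
#' (`"initial"` or `"monitoring"`); `schema` renames non-standard headers.
#' Rows violating a count invariant (germinated > sown, negative or
#' non-integer counts, unparseable dates) are dropped with a diagnostic
#' naming the data row; the diagnostics are attached as the `"problems"`
#' attribute and surfaced as a warning.
#'
#' Replicates of the same lot tested on the same date form one test; the
#' overall percentage of a test is the pooled proportion
#' \eqn{\sum x_i / \sum n_i} (replicates may have unequal `n`), see
#' [summarise_tests()].
#'
#' @param path Path to a CSV file (UTF-8, header row required).
#' @param schema Optional named character vector mapping canonical names
#'   to the file's column names, e.g. `c(lot_id = "accession")`.
#' @return A tibble with the canonical columns, one row per replicate,
#'   ordered by lot, date, replicate. An empty file yields a zero-row
#'   tibble.
#' @seealso [write_germination_tests()], [transition_summary()]
#' @export
read_germination_tests <- function(path, schema = NULL) {
  canonical <- c("lot_id", "test_date", "replicate", "n_sown",
                 "n_germinated", "pretreatment", "test_kind")
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(empty_tests())
  }
  raw <- apply_schema(raw, schema, canonical)
  missing <- setdiff(c("lot_id", "test_date", "n_sown", "n_germinated"), names(raw))
  if (length(missing)) {
    abort(paste0("Missing required columns: ", paste(missing, collapse = ", ")))
  }
  if (!"replicate" %in% names(raw)) raw$replicate <- NA_character_
  if (!"pretreatment" %in% names(raw)) raw$pretreatment <- NA_character_
  if (!"test_kind" %in% names(raw)) raw$test_kind <- "monitoring"

  parsed <- tibble::tibble(
    row = seq_len(nrow(raw)),
    lot_id = raw$lot_id,
    test_date = as.Date(raw$test_date, format = "%Y-%m-%d"),
    replicate = suppressWarnings(as.integer(raw$replicate)),
    n_sown = suppressWarnings(as.numeric(raw$n_sown)),
    n_germinated = suppressWarnings(as.numeric(raw$n_germinated)),
    pretreatment = raw$pretreatment,
    test_kind = raw$test_kind
  )
  problems <- row_problems(parsed)
  keep <- !parsed$row %in% problems$row
  out <- parsed[keep, ] |>
    dplyr::mutate(
      replicate = dplyr::if_else(is.na(.data$replicate), 1L, .data$replicate),
      n_sown = as.integer(.data$n_sown),
      n_germinated = as.integer(.data$n_germinated)
    ) |>
    dplyr::select(-"row") |>
    dplyr::arrange(.data$lot_id, .data$test_date, .data$replicate)
  if (nrow(problems)) {
    warn(paste0(nrow(problems), " row(s) rejected:\n",
                paste0("  row ", problems$row, ": ", problems$message,
                       collapse = "\n")))
  }
  attr(out, "problems") <- problems
  out
}

empty_tests <- function() {
  tibble::tibble(
    lot_id = character(), test_date = as.Date(character()),
    replicate = integer(), n_sown = integer(), n_germinated = integer(),
    pretreatment = character(), test_kind = character()
  )
}

apply_schema <- function(raw, schema, canonical) {
  if (is.null(schema)) return(raw)
  bad <- setdiff(names(schema), canonical)
  if (length(bad)) {
    abort(paste0("Unknown schema keys: ", paste(bad, collapse = ", ")))
  }
  for (canon in names(schema)) {
    if (!schema[[canon]] %in% names(raw)) {
      abort(paste0("Schema column `", schema[[canon]], "` not in file."))
    }
    names(raw)[names(raw) == schema[[canon]]] <- canon
  }
  raw
}

row_problems <- function(parsed) {
  msgs <- list()
  bad <- function(cond, message) {
    rows <- parsed$row[which(cond)]
    if (length(rows)) tibble::tibble(row = rows, message = message)
  }
  out <- dplyr::bind_rows(
    tibble::tibble(row = integer(), message = character()),
    bad(is.na(parsed$lot_id) | parsed$lot_id == "", "missing lot_id"),
    bad(is.na(parsed$test_date), "unparseable test_date (expected YYYY-MM-DD)"),
    bad(is.na(parsed$n_sown) | parsed$n_sown < 1 |
          parsed$n_sown != floor(parsed$n_sown), "n_sown must be a positive integer"),
    bad(is.na(parsed$n_germinated) | parsed$n_germinated < 0 |
          parsed$n_germinated != floor(parsed$n_germinated),
        "n_germinated must be a non-negative integer"),
    bad(!is.na(parsed$n_sown) & !is.na(parsed$n_germinated) &
          parsed$n_germinated > parsed$n_sown,
        "n_germinated exceeds n_sown")
  )
  out |>
    dplyr::distinct(.data$row, .keep_all = TRUE) |>
    dplyr::arrange(.data$row)
}

#' Write germination test records to CSV
#'
#' Inverse of [read_germination_tests()]: writes the canonical columns so
#' that reading the file back reproduces the input tibble.
#'
#' @param tests A tibble as returned by [read_germination_tests()] or
#'   [simulate_test()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_germination_tests <- function(tests, path) {
  cols <- c("lot_id", "test_date", "replicate", "n_sown", "n_germinated",
            "pretreatment", "test_kind")
  readr::write_csv(tests[, cols], path, progress = FALSE)
  invisible(path)
}

#' Read or write storage-experiment observations
#'
#' Storage experiments (controlled ageing) are recorded one row per
#' sampled packet: `lot_id`, `day` (days of experimental storage),
#' `n_sown`, `n_germinated`, plus the experiment-level `moisture_pct`
#' (percent fresh weight) and `temperature_c`. Counts are validated as in
#' [read_germination_tests()]; a lot needs at least two distinct days to
#' be fittable by [fit_probit()].
#'
#' @param path CSV path.
#' @return A tibble, one row per observation, sorted by lot and day.
#' @export
read_storage_experiments <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0) {
    return(tibble::tibble(
      lot_id = character(), day = numeric(), n_sown = integer(),
      n_germinated = integer(), moisture_pct = numeric(),
      temperature_c = numeric()
    ))
  }
  need <- c("lot_id", "day", "n_sown", "n_germinated")
  missing <- setdiff(need, names(raw))
  if (length(missing)) {
    abort(paste0("Missing required columns: ", paste(missing, collapse = ", ")))
  }
  out <- tibble::tibble(
    lot_id = raw$lot_id,
    day = as.numeric(raw$day),
    n_sown = as.integer(raw$n_sown),
    n_germinated = as.integer(raw$n_germinated),
    moisture_pct = if ("moisture_pct" %in% names(raw)) as.numeric(raw$moisture_pct) else NA_real_,
    temperature_c = if ("temperature_c" %in% names(raw)) as.numeric(raw$temperature_c) else NA_real_
  )
  if (any(is.na(out$day) | out$day < 0)) {
    abort("`day` must be non-negative.")
  }
  check_counts(out$n_sown, out$n_germinated)
  dplyr::arrange(out, .data$lot_id, .data$day)
}

#' @rdname read_storage_experiments
#' @param experiments A storage-experiment tibble.
#' @export
write_storage_experiments <- function(experiments, path) {
  cols <- c("lot_id", "day", "n_sown", "n_germinated", "moisture_pct",
            "temperature_c")
  readr::write_csv(experiments[, cols], path, progress = FALSE)
  invisible(path)
}

#' Pooled percentage per germination test
#'
#' Collapses replicate rows to one row per test (lot and date) with the
#' pooled germination percentage \eqn{100 \sum x_i / \sum n_i}.
#'
#' @param tests A germination-test tibble (one row per replicate).
#' @return A tibble with `lot_id`, `test_date`, `test_kind`, `n_sown`,
#'   `n_germinated`, `pct`.
#' @export
summarise_tests <- function(tests) {
  tests |>
    dplyr::group_by(.data$lot_id, .data$test_date) |>
    dplyr::summarise(
      test_kind = dplyr::first(.data$test_kind),
      n_sown = sum(.data$n_sown),
      n_germinated = sum(.data$n_germinated),
      .groups = "drop"
    ) |>
    dplyr::mutate(pct = 100 * .data$n_germinated / .data$n_sown)
}

#' Transition summary of repeat monitoring results
#'
#' For every pair of tests on the same lot whose lag falls in
#' `lag_years`, groups by the original test's rounded percentage and
#' tabulates where the subsequent result landed: at or below the
#' viability standard, above it, and at or above the original result.
#' This is the retrospective view a genebank uses to ask "when the last
#' test said 86%, how often was the lot effectively lost by the next
#' test?" — the answer motivates shortening intervals only in a narrow
#' warning band just above the standard.
#'
#' Percentages are pooled per test and rounded half-up to integers; the
#' lag is counted in whole elapsed years, qualifying when it lies in
#' `[lag_years[1], lag_years[2]]`. All qualifying ordered pairs
#' contribute, so a lot tested three times can contribute several pairs.
#'
#' @param tests A germination-test tibble (one row per replicate).
#' @param threshold_pct Viability standard, default 85.
#' @param lag_years Length-2 numeric, the inclusive window of whole years
#'   between paired tests, default `c(4, 6)`.
#' @return A tibble with one row per original percent: `original_pct`,
#'   `n_pairs`, `prop_le_threshold`, `prop_ge_threshold_plus1`,
#'   `prop_ge_original`. The first two proportions sum to 1 by
#'   construction. No qualifying pairs yields a zero-row tibble.
#' @export
transition_summary <- function(tests, threshold_pct = 85, lag_years = c(4, 6)) {
  stopifnot(length(lag_years) == 2, lag_years[1] <= lag_years[2])
  per_test <- summarise_tests(tests) |>
    dplyr::mutate(pct_int = round_half_up(.data$pct))
  pairs <- per_test |>
    dplyr::inner_join(per_test, by = "lot_id", suffix = c("_orig", "_next"),
                      relationship = "many-to-many") |>
    dplyr::filter(.data$test_date_next > .data$test_date_orig) |>
    dplyr::mutate(lag_whole_years = floor(as.numeric(
      .data$test_date_next - .data$test_date_orig) / DAYS_PER_YEAR + 1e-9)) |>
    dplyr::filter(.data$lag_whole_years >= lag_years[1],
                  .data$lag_whole_years <= lag_years[2])
  if (nrow(pairs) == 0) {
    return(tibble::tibble(
      original_pct = numeric(), n_pairs = integer(),
      prop_le_threshold = numeric(), prop_ge_threshold_plus1 = numeric(),
      prop_ge_original = numeric()
    ))
  }
  pairs |>
    dplyr::group_by(original_pct = .data$pct_int_orig) |>
    dplyr::summarise(
      n_pairs = dplyr::n(),
      prop_le_threshold = mean(.data$pct_int_next <= threshold_pct),
      prop_ge_threshold_plus1 = mean(.data$pct_int_next >= threshold_pct + 1),
      prop_ge_original = mean(.data$pct_int_next >= .data$pct_int_orig),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$original_pct)
}
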