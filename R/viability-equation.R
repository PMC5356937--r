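#' Species constants for the seed viability equation
#'
#' The Ellis–Roberts improved viability equation predicts the probit
#' rate of viability loss from storage conditions:
#' \deqn{\log_{10}\sigma = K_E - C_W \log_{10} m - C_H t - C_Q t^2}
#' with `m` percent fresh-weight moisture content and `t` storage
#' temperature in °C. The four constants are species (or variety-group)
#' properties determined experimentally and published for only a handful
#' of species; this package deliberately ships none — users supply their
#' own, with provenance, via a YAML config:
#'
#' ```yaml
#' species:
#'   my_species:
#'     KE: 9.661
#'     CW: 5.896
#'     CH: 0.04
#'     CQ: 0.000428
#'     source: "where these numbers came from"
#' ```
#'
#' @param path Path to the YAML file.
#' @return A tibble with `species`, `KE`, `CW`, `CH`, `CQ`, `source`.
#' @export
read_species_constants <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species) || !length(cfg$species)) {
    abort("Config has no `species` entries.")
  }
  purrr::imap(cfg$species, function(entry, name) {
    need <- c("KE", "CW", "CH", "CQ")
    missing <- setdiff(need, names(entry))
    if (length(missing)) {
      abort(paste0("Species `", name, "` is missing constants: ",
                   paste(missing, collapse = ", ")))
    }
    vals <- vapply(entry[need], as.numeric, numeric(1))
    if (any(!is.finite(vals))) {
      abort(paste0("Species `", name, "` has non-finite constants."))
    }
    tibble::tibble(
      species = name, KE = vals[["KE"]], CW = vals[["CW"]],
      CH = vals[["CH"]], CQ = vals[["CQ"]],
      source = entry$source %||% NA_character_
    )
  }) |>
    dplyr::bind_rows()
}

#' Predict the probit rate of viability loss from storage conditions
#'
#' Evaluates \eqn{\sigma = 10^{K_E - C_W \log_{10} m - C_H t - C_Q t^2}}
#' days per probit for each row of a constants table at the given
#' conditions. Larger moisture or temperature shortens `sigma` for
#' orthodox seed (positive `CW`, `CH`, `CQ`).
#'
#' @param constants A tibble with `KE`, `CW`, `CH`, `CQ` (and usually
#'   `species`), as from [read_species_constants()].
#' @param moisture_pct Moisture content, percent fresh weight. Must be
#'   positive.
#' @param temperature_c Storage temperature, °C.
#' @return The input tibble with `moisture_pct`, `temperature_c` and
#'   `sigma_days` columns appended.
#' @examples
#' k <- tibble::tibble(species = "demo", KE = 2, CW = 1, CH = 0, CQ = 0)
#' predict_sigma(k, moisture_pct = 10, temperature_c = 3)  # sigma = 10
#' @export
predict_sigma <- function(constants, moisture_pct, temperature_c) {
  if (any(moisture_pct <= 0)) abort("`moisture_pct` must be positive.")
  constants |>
    dplyr::mutate(
      moisture_pct = moisture_pct,
      temperature_c = temperature_c,
      sigma_days = 10^(.data$KE - .data$CW * log10(moisture_pct) -
                         .data$CH * temperature_c - .data$CQ * temperature_c^2)
    )
}

#' Predicted survival curve
#'
#' Percent viability over storage time for given initial viability `Ki`
#' (probits), probit rate `sigma` (days), and non-responding fraction
#' `f`: \eqn{100\,(1-f)\,\Phi(K_i - d/\sigma)}. With `f > 0` the curve
#' plateaus at \eqn{100(1-f)} near day 0 instead of approaching 100%.
#'
#' @param Ki Initial viability, probits.
#' @param sigma Days per probit, positive.
#' @param days Numeric vector of storage days.
#' @param f Non-responder proportion in `[0, 1)`, default 0.
#' @return A tibble with `day` and `viability_pct`.
#' @export
predict_survival <- function(Ki, sigma, days, f = 0) {
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (f < 0 || f >= 1) abort("`f` must be in [0, 1).")
  if (any(days < 0)) abort("`days` must be non-negative.")
  tibble::tibble(
    day = days,
    viability_pct = 100 * (1 - f) * pnorm(Ki - days / sigma)
  )
}

#' Predicted time for viability to fall between two levels
#'
#' Days of storage for viability to decline from a starting level
#' (given in probits) to a target percentage, on a survival line with
#' rate `sigma`: \eqn{d = \sigma\,(K_{start} - \Phi^{-1}(p_{target}))}.
#' This is the quantity behind monitoring-interval rules such as
#' "predicted time from 88% to 85%".
#'
#' @param Ki_start Starting viability, probits.
#' @param target_pct Target viability percent, strictly below the
#'   starting percent.
#' @param sigma Days per probit.
#' @return Days, a numeric scalar.
#' @examples
#' time_between_viabilities(pct_to_probit(88), 85, sigma = 365)
#' @export
time_between_viabilities <- function(Ki_start, target_pct, sigma) {
  if (sigma <= 0) abort("`sigma` must be positive.")
  target_probit <- pct_to_probit(target_pct)
  if (target_probit >= Ki_start) {
    abort("`target_pct` must be below the starting viability.")
  }
  sigma * (Ki_start - target_probit)
}

#' Plot predicted survival curves
#'
#' Draws one survival curve per row of a parameter table — the standard
#' picture for comparing lots of different initial viability or
#' non-responder fraction under common storage conditions.
#'
#' @param params A tibble with columns `Ki`, `sigma`, optional `f` and a
#'   label column `lot_id` (or `species`).
#' @param horizon_days Right edge of the time axis; default
#'   `3 * max(sigma * Ki)`.
#' @return A ggplot.
#' @export
plot_survival_curves <- function(params, horizon_days = NULL) {
  if (!"f" %in% names(params)) params$f <- 0
  label_col <- intersect(c("lot_id", "species"), names(params))[1]
  if (is.na(label_col)) {
    params$lot_id <- paste0("curve", seq_len(nrow(params)))
    label_col <- "lot_id"
  }
  horizon_days <- horizon_days %||% max(3 * params$sigma * pmax(params$Ki, 1))
  curves <- params |>
    dplyr::rowwise() |>
    dplyr::reframe(
      label = .data[[label_col]],
      predict_survival(.data$Ki, .data$sigma,
                       seq(0, horizon_days, length.out = 200), .data$f)
    )
  ggplot2::ggplot(curves, ggplot2::aes(x = .data$day, y = .data$viability_pct,
                                       colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Storage (days)", y = "Viability (%)", colour = NULL) +
    ggplot2::ylim(0, 100)
}
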