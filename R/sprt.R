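#' Define a Wald sequential test plan for viability monitoring
#'
#' A sequential scheme sows a small batch first and only draws more seed
#' when the cumulative count is inconclusive, deciding between an
#' acceptable viability `p0` and an unacceptable `p1 < p0` with producer
#' risk `alpha` (rejecting a lot truly at `p0`) and consumer risk `beta`
#' (accepting a lot truly at `p1`). Against a fixed-size test it usually
#' spends far fewer seeds, especially while viability is still high.
#'
#' The decision lines on cumulative germinated count `s` against
#' cumulative sown `m` are the Wald lines `s = h + b m` with common slope
#' \deqn{b = \frac{\log\frac{1-p_1}{1-p_0}}
#'   {\log\frac{p_0}{p_1} + \log\frac{1-p_1}{1-p_0}}}
#' and intercepts \eqn{h_a = \log\frac{1-\beta}{\alpha}/D} (accept) and
#' \eqn{h_r = -\log\frac{1-\alpha}{\beta}/D} (reject), `D` the slope
#' denominator. The slope always lies strictly between `p1` and `p0`.
#' Sampling is truncated at `max_seeds`, where the observed proportion is
#' compared against the midpoint `(p0 + p1)/2`.
#'
#' @param p0 Acceptable viability proportion.
#' @param p1 Unacceptable viability proportion, `p1 < p0`.
#' @param alpha,beta Risk probabilities in `(0, 0.5)`, default 0.05.
#' @param batch_size Seeds sown per increment, default 40.
#' @param max_seeds Truncation bound on total seeds, default 200.
#' @return An object of class `sprt_plan`.
#' @examples
#' plan <- sprt_plan(p0 = 0.90, p1 = 0.70)
#' sprt_boundaries(plan, m = c(40, 80, 120))
#' @export
sprt_plan <- function(p0, p1, alpha = 0.05, beta = 0.05,
                      batch_size = 40, max_seeds = 200) {
  check_prob(p0, "p0"); check_prob(p1, "p1")
  if (p1 >= p0) abort("`p1` must be below `p0`.")
  if (alpha <= 0 || alpha >= 0.5 || beta <= 0 || beta >= 0.5) {
    abort("`alpha` and `beta` must lie in (0, 0.5).")
  }
  if (batch_size < 1 || max_seeds < batch_size) {
    abort("`batch_size` must be >= 1 and `max_seeds` >= `batch_size`.")
  }
  D <- log(p0 / p1) + log((1 - p1) / (1 - p0))
  structure(
    list(
      p0 = p0, p1 = p1, alpha = alpha, beta = beta,
      batch_size = as.integer(batch_size), max_seeds = as.integer(max_seeds),
      slope = log((1 - p1) / (1 - p0)) / D,
      h_accept = log((1 - beta) / alpha) / D,
      h_reject = -log((1 - alpha) / beta) / D
    ),
    class = "sprt_plan"
  )
}

#' @export
print.sprt_plan <- function(x, ...) {
  cat(sprintf(
    "Sequential test plan: p0 = %.2f, p1 = %.2f, alpha = %.2f, beta = %.2f\n",
    x$p0, x$p1, x$alpha, x$beta))
  cat(sprintf("  lines: s = %.3f + %.4f m (accept) / s = %.3f + %.4f m (reject)\n",
              x$h_accept, x$slope, x$h_reject, x$slope))
  cat(sprintf("  batches of %d seeds, truncated at %d\n",
              x$batch_size, x$max_seeds))
  invisible(x)
}

#' Decision boundaries of a sequential plan
#'
#' Counts at which the cumulative germinated total triggers a decision
#' after `m` seeds sown: accept when the count reaches
#' `ceiling(h_a + b m)`, reject when it falls to `floor(h_r + b m)`.
#' Boundaries outside `[0, m]` are unreachable at that `m` and returned
#' as `NA`.
#'
#' @param plan An [sprt_plan()].
#' @param m Vector of cumulative seeds sown (each >= 1).
#' @return A tibble with `m`, `accept_line`, `reject_line` (the real
#'   lines) and `accept_count`, `reject_count` (integer triggers, `NA`
#'   when unreachable).
#' @export
sprt_boundaries <- function(plan, m) {
  if (any(m < 1)) abort("`m` must be at least 1.")
  acc_line <- plan$h_accept + plan$slope * m
  rej_line <- plan$h_reject + plan$slope * m
  acc <- ceiling(acc_line)
  rej <- floor(rej_line)
  tibble::tibble(
    m = m,
    accept_line = acc_line, reject_line = rej_line,
    accept_count = ifelse(acc <= m, acc, NA_real_),
    reject_count = ifelse(rej >= 0, rej, NA_real_)
  )
}

#' Evaluate cumulative counts against a sequential plan
#'
#' Walks the observed batches in order, checking the cumulative
#' germinated count against the plan's boundaries after each batch, and
#' returns the first decision reached — `"accept"`, `"reject"`, or
#' `"continue"` if sampling should go on. At or beyond `max_seeds` a
#' forced decision compares the observed proportion with
#' `(p0 + p1) / 2`, so truncation never returns `"continue"`.
#'
#' @param plan An [sprt_plan()].
#' @param counts A tibble with `n_sown` and `n_germinated`, one row per
#'   batch in sampling order. May be empty (decision `"continue"`).
#' @return A one-row tibble: `decision`, `cumulative_sown`,
#'   `cumulative_germinated`, `accept_boundary`, `reject_boundary`
#'   (the counts at the deciding `m`, or at the next batch for an empty
#'   history).
#' @export
sprt_evaluate <- function(plan, counts) {
  if (nrow(counts) == 0) {
    b <- sprt_boundaries(plan, plan$batch_size)
    return(tibble::tibble(
      decision = "continue", cumulative_sown = 0L, cumulative_germinated = 0L,
      accept_boundary = b$accept_line, reject_boundary = b$reject_line
    ))
  }
  check_counts(counts$n_sown, counts$n_germinated)
  m_cum <- cumsum(counts$n_sown)
  s_cum <- cumsum(counts$n_germinated)
  if (max(m_cum) > plan$max_seeds) {
    abort("Cumulative seeds sown exceed the plan's `max_seeds`.")
  }
  for (i in seq_along(m_cum)) {
    b <- sprt_boundaries(plan, m_cum[i])
    if (!is.na(b$accept_count) && s_cum[i] >= b$accept_count) {
      return(decision_row("accept", m_cum[i], s_cum[i], b))
    }
    if (!is.na(b$reject_count) && s_cum[i] <= b$reject_count) {
      return(decision_row("reject", m_cum[i], s_cum[i], b))
    }
  }
  last <- length(m_cum)
  b <- sprt_boundaries(plan, m_cum[last])
  if (m_cum[last] >= plan$max_seeds) {
    forced <- if (s_cum[last] / m_cum[last] >= (plan$p0 + plan$p1) / 2)
      "accept" else "reject"
    return(decision_row(forced, m_cum[last], s_cum[last], b))
  }
  decision_row("continue", m_cum[last], s_cum[last], b)
}

decision_row <- function(decision, m, s, b) {
  tibble::tibble(
    decision = decision, cumulative_sown = as.integer(m),
    cumulative_germinated = as.integer(s),
    accept_boundary = b$accept_line, reject_boundary = b$reject_line
  )
}

#' Expected seed use of a sequential plan
#'
#' Monte-Carlo mean of the seeds sown before the plan reaches a
#' decision, for a lot of true viability `true_p`. This is the number to
#' hold against a fixed-size test (e.g. 200 seeds) when judging whether
#' a sequential scheme saves seed.
#'
#' @param plan An [sprt_plan()].
#' @param true_p True germination probability.
#' @param n_sims Number of simulated lots, default 1000.
#' @param seed RNG seed (local scope), default 1.
#' @return A one-row tibble: `true_p`, `mean_seeds`, `accept_rate`,
#'   `reject_rate`, `n_sims`.
#' @export
sprt_expected_seed_use <- function(plan, true_p, n_sims = 1000, seed = 1) {
  check_prob(true_p, "true_p", open = FALSE)
  res <- with_local_seed(seed, {
    purrr::map(seq_len(n_sims), function(i) {
      counts <- empty_batches()
      repeat {
        remaining <- plan$max_seeds - sum(counts$n_sown)
        batch <- min(plan$batch_size, remaining)
        counts <- dplyr::bind_rows(counts, tibble::tibble(
          n_sown = batch, n_germinated = rbinom(1, batch, true_p)))
        d <- sprt_evaluate(plan, counts)
        if (d$decision != "continue") return(d)
      }
    })
  }) |>
    dplyr::bind_rows()
  tibble::tibble(
    true_p = true_p,
    mean_seeds = mean(res$cumulative_sown),
    accept_rate = mean(res$decision == "accept"),
    reject_rate = mean(res$decision == "reject"),
    n_sims = n_sims
  )
}

empty_batches <- function() {
  tibble::tibble(n_sown = integer(), n_germinated = integer())
}

#' @describeIn sprt_plan Plot the accept/reject lines with the continue
#'   region between them.
#' @param object An `sprt_plan`.
#' @param ... Unused.
#' @method autoplot sprt_plan
#' @export
autoplot.sprt_plan <- function(object, ...) {
  m <- seq(1, object$max_seeds)
  b <- sprt_boundaries(object, m)
  long <- tidyr::pivot_longer(b[, c("m", "accept_line", "reject_line")],
                              -"m", names_to = "line", values_to = "s")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$m, y = .data$s,
                                     colour = .data$line)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Cumulative seeds sown",
                  y = "Cumulative seeds germinated", colour = NULL)
}
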