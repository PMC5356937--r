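#' Modified Jeffreys confidence interval for a germination result
#'
#' Equal-tail interval from the Jeffreys posterior
#' \eqn{\mathrm{Beta}(x + 1/2,\; n - x + 1/2)}, with the boundary
#' modifications of Brown, Cai and DasGupta (2001): when `x = 0` the lower
#' limit is 0 and the upper limit solves \eqn{(1-p)^n = \alpha/2}; when
#' `x = n` the upper limit is 100 and the lower limit solves
#' \eqn{p^n = \alpha/2}. This is the interval genebank practice reports for
#' a germination percentage, and it conveys how little a small sample
#' constrains true lot viability: 23 of 25 seeds germinating (92%) is
#' compatible with anything from about 77% to 98%.
#'
#' @param x Number of germinated seeds (successes). Vectorised.
#' @param n Number of seeds sown (trials). Vectorised along `x`.
#' @param level Nominal coverage, default `0.95`.
#' @return A tibble with columns `x`, `n`, `estimate_pct`, `lower_pct`,
#'   `upper_pct`, `level`. Percentages are unrounded.
#' @examples
#' jeffreys_ci(23, 25)
#' jeffreys_ci(c(195, 585), c(200, 600))
#' @export
jeffreys_ci <- function(x, n, level = 0.95) {
  check_prob(level, "level")
  dat <- tibble::tibble(x = as.numeric(x), n = as.numeric(n))
  if (any(dat$n < 1)) abort("`n` must be at least 1.")
  check_counts(dat$n, dat$x)
  a <- (1 - level) / 2
  lower <- qbeta(a, dat$x + 0.5, dat$n - dat$x + 0.5)
  upper <- qbeta(1 - a, dat$x + 0.5, dat$n - dat$x + 0.5)
  at0 <- dat$x == 0
  atn <- dat$x == dat$n
  # endpoint rules: exact tail-solved limit on the open side, hard 0/1 on
  # the closed side
  lower[at0] <- 0
  upper[at0] <- 1 - a^(1 / dat$n[at0])
  upper[atn] <- 1
  lower[atn] <- a^(1 / dat$n[atn])
  tibble::tibble(
    x = dat$x, n = dat$n,
    estimate_pct = 100 * dat$x / dat$n,
    lower_pct = 100 * lower,
    upper_pct = 100 * upper,
    level = level
  )
}

#' Exact binomial tail probability against a viability standard
#'
#' The exact (summed, not normal-approximated) binomial tail for an
#' observed germination count under a hypothesised lot viability `p0`.
#' With `tail = "upper"` this is \eqn{P(X \ge x \mid n, p_0)} — read as the
#' probability of seeing a result at least this good if the lot were
#' already at the standard. For 23/25 against 85% it is 0.254: a seemingly
#' comfortable 92% result leaves a one-in-four chance the lot is already
#' at or below the regeneration threshold.
#'
#' @param x Germinated count. Vectorised.
#' @param n Seeds sown.
#' @param p0 Hypothesised viability proportion in `[0, 1]`.
#' @param tail `"upper"` for \eqn{P(X \ge x)}, `"lower"` for
#'   \eqn{P(X \le x)}.
#' @return A tibble with columns `x`, `n`, `p0`, `tail`, `p_value`.
#' @examples
#' exact_binomial_tail(23, 25, 0.85)
#' @export
exact_binomial_tail <- function(x, n, p0, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  check_prob(p0, "p0", open = FALSE)
  dat <- tibble::tibble(x = as.numeric(x), n = as.numeric(n))
  check_counts(dat$n, dat$x)
  p <- if (tail == "upper") {
    pbinom(dat$x - 1, dat$n, p0, lower.tail = FALSE)
  } else {
    pbinom(dat$x, dat$n, p0)
  }
  tibble::tibble(x = dat$x, n = dat$n, p0 = p0, tail = tail, p_value = p)
}

#' Convert between probits (NED) and percentage viability
#'
#' Viability analysis works on the probit scale: the normal equivalent
#' deviate \eqn{v = \Phi^{-1}(p)}. `probit_to_pct()` returns
#' \eqn{100\,\Phi(v)}; `pct_to_probit()` is its inverse. 0 probits is 50%,
#' 1.960 probits is 97.5%, and the transform stretches the 85–100% band
#' where genebank data live.
#'
#' @param v Viability in probits (NED). Vectorised.
#' @param pct Viability percent, strictly between 0 and 100. Vectorised.
#' @return A numeric vector.
#' @examples
#' probit_to_pct(c(0, 1.960, 2.984))
#' pct_to_probit(85)
#' @export
probit_to_pct <- function(v) {
  100 * pnorm(v)
}

#' @rdname probit_to_pct
#' @export
pct_to_probit <- function(pct) {
  if (any(pct <= 0 | pct >= 100)) {
    abort("`pct` must be strictly between 0 and 100 (0 and 100 map to infinite probits).")
  }
  qnorm(pct / 100)
}
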