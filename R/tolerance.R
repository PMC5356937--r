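#' Tolerance test for replicated germination counts
#'
#' When a germination sample is sown as several replicates, some spread
#' between replicate counts is expected from binomial sampling alone.
#' Published tolerance tables give the maximal acceptable range; this
#' function computes the same decision from first principles. The null
#' model draws each replicate independently as
#' \eqn{X_i \sim \mathrm{Binomial}(n_i, \hat p)} with \eqn{\hat p} the
#' pooled proportion, and the p-value is the null probability of a range
#' (max − min germinated) at least as large as observed. A test fails
#' tolerance when that probability is at or below `alpha` — the result
#' spread is then unlikely to be sampling noise and the whole test
#' should be repeated.
#'
#' `method = "exact"` computes the null range distribution exactly (a
#' sum over the minimum count of products of binomial CDF differences —
#' equivalent to enumerating the joint outcome space, but far cheaper).
#' `method = "montecarlo"` estimates it from `n_draws` simulated
#' replicate sets under a fixed, overridable seed.
#'
#' The tolerated range is widest at 50% pooled germination and shrinks
#' toward 0% or 100%; with a degenerate pooled proportion (0 or 1) the
#' null is a point mass and only a zero range is in tolerance.
#'
#' @param replicates A tibble with columns `n_sown` and `n_germinated`,
#'   one row per replicate (at least two; unequal `n_sown` allowed).
#' @param alpha Significance probability, default 0.05 (the conventional
#'   "5% probability" of tolerance tables).
#' @param method `"exact"` (default) or `"montecarlo"`.
#' @param n_draws Monte-Carlo draws, default `1e5`.
#' @param mc_seed Monte-Carlo seed, default 20170304; the draw is made in
#'   a local RNG scope so the caller's random stream is untouched.
#' @return A one-row tibble: `n_replicates`, `pooled_pct`,
#'   `observed_range`, `tolerated_range`, `p_value`, `in_tolerance`,
#'   `alpha`, `method`.
#' @examples
#' tolerance_test(tibble::tibble(n_sown = c(100, 100),
#'                               n_germinated = c(98, 92)))
#' @export
tolerance_test <- function(replicates, alpha = 0.05,
                           method = c("exact", "montecarlo"),
                           n_draws = 1e5, mc_seed = 20170304) {
  method <- match.arg(method)
  check_prob(alpha, "alpha")
  n <- replicates$n_sown
  x <- replicates$n_germinated
  if (length(n) < 2) abort("Need at least 2 replicates for a tolerance test.")
  check_counts(n, x)
  p_hat <- sum(x) / sum(n)
  obs_range <- max(x) - min(x)

  if (p_hat %in% c(0, 1)) {
    return(tibble::tibble(
      n_replicates = length(n), pooled_pct = 100 * p_hat,
      observed_range = obs_range, tolerated_range = 0L,
      p_value = as.numeric(obs_range == 0),
      in_tolerance = obs_range == 0, alpha = alpha, method = method
    ))
  }

  if (method == "exact") {
    top <- max(n)
    if (prod(n + 1) <= 1e6) {
      # small outcome space: enumerate the joint pmf in full precision
      joint <- expand.grid(lapply(n, function(ni) 0:ni))
      probs <- Reduce(`*`, lapply(seq_along(n), function(i) {
        dbinom(joint[[i]], n[i], p_hat)
      }))
      rng <- do.call(pmax, joint) - do.call(pmin, joint)
      mass <- vapply(0:top, function(r) sum(probs[rng == r]), numeric(1))
      tail_ge <- rev(cumsum(rev(mass)))  # element r+1 is P(range >= r)
      p_value <- tail_ge[obs_range + 1]
      exceed <- c(tail_ge[-1], 0)       # element r+1 is P(range > r)
    } else {
      cdf_range <- range_cdf(n, p_hat)  # element r+1 is P(range <= r)
      p_value <- if (obs_range == 0) 1 else 1 - cdf_range[obs_range]
      exceed <- 1 - cdf_range
    }
    tolerated <- which(exceed <= alpha)[1] - 1L
  } else {
    draws <- with_local_seed(mc_seed, {
      sim <- vapply(seq_along(n), function(i) rbinom(n_draws, n[i], p_hat),
                    numeric(n_draws))
      apply(sim, 1, max) - apply(sim, 1, min)
    })
    p_value <- mean(draws >= obs_range)
    # smallest R with P(range > R) <= alpha
    tolerated <- which(vapply(0:max(n), function(r) mean(draws > r),
                              numeric(1)) <= alpha)[1] - 1L
  }
  tibble::tibble(
    n_replicates = length(n), pooled_pct = 100 * p_hat,
    observed_range = obs_range, tolerated_range = as.integer(tolerated),
    p_value = p_value, in_tolerance = p_value > alpha,
    alpha = alpha, method = method
  )
}

# P(max X_i - min X_i <= r) for independent X_i ~ Binomial(n_i, p),
# r = 0..max(n_i). Decomposes on the value of the minimum:
# P(all in [m, m+r], min = m) = prod(F(m+r) - F(m-1)) - prod(F(m+r) - F(m)).
range_cdf <- function(n, p) {
  top <- max(n)
  vapply(0:top, function(r) {
    total <- 0
    for (m in 0:top) {
      hi <- pmin(m + r, n)
      in_band <- mapply(function(ni, hii) pbinom(hii, ni, p) - pbinom(m - 1, ni, p),
                        n, hi)
      above_m <- mapply(function(ni, hii) pbinom(hii, ni, p) - pbinom(m, ni, p),
                        n, hi)
      total <- total + prod(pmax(in_band, 0)) - prod(pmax(above_m, 0))
    }
    min(total, 1)
  }, numeric(1))
}

with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Tolerance comparison of two whole germination tests
#'
#' Pools each test to a single pseudo-replicate and applies
#' [tolerance_test()] — the check used to flag discordant paired tests,
#' e.g. the same sample germinated with and without a pretreatment, or
#' duplicate tests by independent laboratories.
#'
#' @param test_a,test_b Tibbles of replicates (`n_sown`,
#'   `n_germinated`), each describing one complete test.
#' @inheritParams tolerance_test
#' @return As [tolerance_test()], computed on the two pooled counts.
#' @export
tolerance_of_pair <- function(test_a, test_b, alpha = 0.05,
                              method = c("exact", "montecarlo")) {
  if (nrow(test_a) == 0 || nrow(test_b) == 0) {
    abort("Both tests must contain at least one replicate.")
  }
  pooled <- tibble::tibble(
    n_sown = c(sum(test_a$n_sown), sum(test_b$n_sown)),
    n_germinated = c(sum(test_a$n_germinated), sum(test_b$n_germinated))
  )
  tolerance_test(pooled, alpha = alpha, method = method)
}
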