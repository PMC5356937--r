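# Independent oracles, coded without reference to the package internals.

# Binomial probit regression by hand-rolled IRLS (Fisher scoring on the
# working response), independent of stats::glm.
irls_probit <- function(day, n, x, tol = 1e-12, maxit = 200) {
  X <- cbind(1, day)
  p_emp <- pmin(pmax(x / n, 0.01), 0.99)
  beta <- qr.solve(X, qnorm(p_emp))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- pnorm(eta)
    mu <- pmin(pmax(mu, 1e-10), 1 - 1e-10)
    d <- dnorm(eta)
    w <- n * d^2 / (mu * (1 - mu))
    z <- eta + (x / n - mu) / d
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) {
      return(drop(beta_new))
    }
    beta <- drop(beta_new)
  }
  drop(beta)
}

# Brute-force tolerance p-value: enumerate the full joint outcome space of
# independent Binomial(n_i, p) replicates.
enumerate_range_pvalue <- function(n, p, observed_range) {
  grids <- lapply(n, function(ni) 0:ni)
  joint <- expand.grid(grids)
  probs <- Reduce(`*`, lapply(seq_along(n), function(i) {
    dbinom(joint[[i]], n[i], p)
  }))
  ranges <- do.call(pmax, joint) - do.call(pmin, joint)
  sum(probs[ranges >= observed_range])
}

# Wald's sequential boundary lines, coded directly from the plan risks.
wald_lines <- function(p0, p1, alpha, beta, m) {
  g1 <- log(p0 / p1)
  g0 <- log((1 - p1) / (1 - p0))
  denom <- g1 + g0
  list(
    accept = log((1 - beta) / alpha) / denom + g0 / denom * m,
    reject = -log((1 - alpha) / beta) / denom + g0 / denom * m
  )
}

# Spearman rank correlation via base R on plain vectors.
spearman <- function(a, b) cor(a, b, method = "spearman")

write_temp_csv <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
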