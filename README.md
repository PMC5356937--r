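# viamon — statistics for seed genebank viability monitoring

Genebanks keep crop diversity alive as stored seed. Accessions must be
germination-tested periodically and regenerated before viability falls
below the standard (conventionally 85%), but every test destroys seed
and a percentage estimated from a small sample is far less certain than
it looks. viamon is an R toolkit for the statistics of that workflow,
aimed at genebank managers and seed scientists:

* **Binomial inference on a single test** — modified-Jeffreys
  confidence intervals (`jeffreys_ci()`) and exact binomial tail tests
  against a viability standard (`exact_binomial_tail()`), plus
  probit ↔ percent conversion.
* **Probit survival analysis of storage experiments** — fit
  `v = Ki − d/σ` (viability in probits after `d` days; `Ki` the initial
  viability in probits, `σ` the days per probit of decline) by binomial
  GLM (`fit_probit()`), with an optional never-germinating fraction
  `f`; percentile storage times `p85`/`p50` with delta-method or
  Fieller limits (`percentile_time()`); longevity ranking
  (`rank_by_percentile()`).
* **Viability-equation predictions** — `σ` from user-supplied
  Ellis–Roberts species constants,
  `log10 σ = KE − CW·log10 m − CH·t − CQ·t²` (`predict_sigma()`),
  survival curves and times between viability levels.
* **Tolerance testing of replicates** — is the spread between replicate
  counts explicable by binomial sampling? (`tolerance_test()`).
* **Sequential test plans** — Wald SPRT accept/reject boundaries on
  cumulative counts, saving seed when viability is still high
  (`sprt_plan()`, `sprt_evaluate()`).
* **Monitoring schedules** — one-third-of-time-to-threshold interval
  rules, warning-band revision, longevity-batch scheduling
  (`monitoring_policy()`, `initial_interval()`, `update_after_result()`,
  `batch_schedule()`).
* **A simulator** — cohorts, storage experiments and multi-decade
  monitoring histories with known ground truth
  (`simulate_cohort()`, `simulate_history()`).

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on fits, `autoplot()` on fits and plans.

## A worked example

How much does a 25-seed test really tell you?

```r
library(viamon)

jeffreys_ci(23, 25)
#>       x     n estimate_pct lower_pct upper_pct level
#> 1    23    25           92      76.7      98.3  0.95

exact_binomial_tail(23, 25, p0 = 0.85)
#>       x     n    p0 tail  p_value
#> 1    23    25  0.85 upper   0.254
```

23 of 25 seeds germinating reads as 92%, but the 95% interval runs from
76.7% to 98.3% — and if the lot were already at the 85% regeneration
standard, a result at least this high would still occur with
probability 0.254. A small monitoring test simply cannot distinguish a
healthy lot from one at the threshold.

A storage experiment pins the survival curve down instead. Here a
simulated experiment (10 sampling days, 100 seeds each, true
`Ki = 2.9`, `σ = 6`):

```r
exp <- simulate_storage_experiment(Ki = 2.9, sigma = 6,
                                   days = seq(0, 27, 3), n_per_day = 100,
                                   seed = 7, lot_id = "DEMO01")
fit <- fit_probit(exp)
fit
#> Probit survival fit (lot DEMO01)
#>   Ki    = 3.015 probits (99.872%)
#>   sigma = 5.675 days per probit
#>   10 observations, deviance 17.05 on 8 df

percentile_time(fit, 85)
#>   percentile_pct  days lower_days upper_days level method
#> 1             85  11.2       10.4       12.1  0.95 delta
```

The fitted initial viability is 99.87% probits-side, and viability is
estimated to reach 85% after 11.2 days of experimental storage (95%
limits 10.4–12.1) — the number used to rank lots for testing order and
to set monitoring intervals (one-third of the predicted time to the
standard):

```r
initial_interval(monitoring_policy(), Ki = 2.9, sigma_days = 3000)
#>   next_test_day interval_days ... rationale
#> 1         1864.         1864.     third_to_absolute_standard: ...
```

And when replicates disagree more than binomial sampling allows, the
tolerance test says so:

```r
tolerance_test(tibble::tibble(n_sown = c(100, 100),
                              n_germinated = c(98, 88)))
#>   pooled_pct observed_range tolerated_range p_value in_tolerance
#> 1         93             10               7 0.00876 FALSE
```

A range of 10 between two 100-seed replicates at 93% pooled germination
has null probability 0.009 — the whole test should be repeated.

See `vignette("viability-monitoring")` for the models, their
assumptions and the package's design choices, and `inst/cli/viamon` for
a thin command-line front end over the same functions.

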