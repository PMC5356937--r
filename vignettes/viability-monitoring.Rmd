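---
title: "Statistical methods for seed genebank viability monitoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods for seed genebank viability monitoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(viamon)
library(dplyr)
```

Seed genebanks conserve crop diversity as dried seed in cold storage. The
seeds age, so each accession's germination capacity is tested periodically
and the lot is regenerated (grown out to produce fresh seed) before
viability falls below a standard, conventionally 85%. Each test destroys
seed and costs labour, and a germination percentage estimated from 25 or
50 seeds is a much blunter instrument than it looks. viamon collects the
statistical machinery a genebank needs to take these decisions honestly:
interval estimates for single results, survival-curve fitting for storage
experiments, predictions from the seed viability equation, tolerance
checks on replicates, sequential test plans, and a schedule planner —
plus a simulator that generates cohorts with known ground truth so that
every procedure can be validated end to end.

## The probit model of seed survival

The core model is a straight line on the probit scale. With
$\Phi$ the standard normal CDF, viability after $d$ days of storage is

$$v(d) = K_i - d/\sigma \quad \text{(probits)}, \qquad
  \text{percent}(d) = 100\,\Phi(v(d)),$$

where $K_i$ is the theoretical initial viability in probits and $\sigma$
is the number of days for viability to fall by one probit. The model
reflects the empirical finding that seed death times in a lot are close
to normally distributed: survival curves are sigmoid in time, flat while
the lot is far from its mean death time, then steep. Two consequences
matter for monitoring. First, a high $K_i$ mostly buys a longer lag
before decline rather than a different decline rate. Second, percentages
compress near 100%, so the probit scale — not the percent scale — is
where inference is linear and well behaved.

`fit_probit()` estimates $(K_i, \sigma)$ by maximum-likelihood binomial
regression with a probit link (`stats::glm`), i.e. full binomial ML
rather than the older transformed-least-squares probit workflow.
Observations at 0% or 100% germination are kept: the binomial likelihood
handles them exactly, and dropping late all-dead samples would bias
$\sigma$ upward. A fit is refused, with an explanatory error, when fewer
than two distinct sampling days exist or when *every* observation is at
0% or 100% (complete separation — the slope is then unidentifiable). We
run the IWLS to a tight tolerance (`epsilon = 1e-12`) so that fits agree
with an independent implementation to about `1e-6`; because the deviance
can oscillate at machine precision under so tight a criterion, apparent
non-convergence is re-checked with a score test (one further Newton step
must move the coefficients by less than `1e-8`) before an error is
raised.

### Non-responders

Some lots contain a fraction $f$ of seeds that were never able to
germinate (empty florets, pre-storage damage) and are not part of the
ageing population. The observed proportion is then
$(1-f)\,\Phi(K_i - d/\sigma)$: a plateau below 100% at day 0. With
`include_nonresponders = TRUE`, $f$ is estimated by profiling the
likelihood on a grid over $[0, 0.5]$ (step 0.02) and refining the best
grid point with `optimize()`. We profile rather than take joint Newton
steps because the boundary $f = 0$, where most lots live, makes the
joint Hessian ill-conditioned; the reported covariance for
$(K_i, \text{slope})$ is the profile covariance at $\hat f$. Recovering
$f$ needs data past the plateau — at 200 seeds per time point a true
$f = 0.10$ is typically recovered within $\pm 0.05$.

### Percentile times and their limits

The time to any viability percentile is linear in the parameters on the
probit scale, $p_q = \sigma\,(K_i - \Phi^{-1}(q))$, with $q$ the target
proportion *of the responding fraction*. `percentile_time()` reports
delta-method Wald limits by default; Fieller's construction is available
behind a flag for fits whose slope is poorly determined (the delta
interval is symmetric and can be optimistic there; Fieller solves the
defining quadratic and degenerates honestly to an unbounded interval
when the slope is not distinguishable from zero). The default is the
delta method because for realistic storage-experiment designs (6–10
sampling days, 50–200 seeds each) the two agree to a few percent.

## Uncertainty of a single germination test

For a single test of $x$ germinated out of $n$ sown, `jeffreys_ci()`
gives the equal-tail interval of the Beta$(x+\tfrac12, n-x+\tfrac12)$
posterior — the modified Jeffreys interval, with endpoint rules at
$x = 0$ and $x = n$ (the closed side pinned to 0 or 100% and the open
side solved exactly from the binomial tail). This interval has close to
nominal coverage even at small $n$ and extreme proportions, where the
Wald interval fails completely. The companion `exact_binomial_tail()`
sums the binomial pmf — no normal approximation — to answer questions
such as: given 23/25 germinated (92%), how probable is a result at
least this high if the lot were already at the 85% standard? The answer,
0.254, is the cautionary tale of small-sample monitoring: one test in
four of a lot *at the regeneration threshold* would look this healthy.

## The seed viability equation

When storage experiments are impractical, the Ellis–Roberts viability
equation predicts $\sigma$ from conditions:
$\log_{10}\sigma = K_E - C_W\log_{10} m - C_H t - C_Q t^2$, with $m$
percent fresh-weight moisture and $t$ °C. The four constants are
species- or variety-group-specific and published for only a handful of
taxa; viamon ships **none** and loads user-supplied values (with a
provenance string) from a YAML config, because bundling constants the
user has not vetted would silently anchor every downstream schedule.
Moisture is interpreted on the fresh-weight basis throughout; no
wet/dry-basis conversion is attempted. Known limitation: the equation
assumes all lots of a species share $\sigma$ under given conditions,
which real cohorts violate — the package's storage-experiment route
exists precisely because of that lot-to-lot variation.

## Tolerance of replicate counts

`tolerance_test()` asks whether the spread among replicate counts is
compatible with binomial sampling. The null model draws each replicate
independently as Binomial$(n_i, \hat p)$ with $\hat p$ the pooled
proportion (a plug-in, unconditional null — the structure implicit in
published range-based tolerance tables), and the p-value is the null
probability of a count range at least as large as observed. When the
joint outcome space has at most $10^6$ points it is enumerated exactly;
beyond that, an exact decomposition of the range distribution over the
minimum count is used, and a Monte-Carlo method (fixed, overridable
seed; $10^5$ draws) is available as a cross-check. The tolerated range
is widest at 50% germination and shrinks toward the extremes; because
counts are discrete the test is conservative, rejecting somewhat less
often than $\alpha$. A conditional (multinomial) null is a recognised
alternative; it is deliberately not the default, and no claim is made
of bit-exact agreement with any historical printed table.

## Sequential test plans

`sprt_plan()` implements Wald's sequential probability ratio test on
cumulative germination counts, deciding between an acceptable viability
$p_0$ and an unacceptable $p_1 < p_0$. The accept/reject lines share the
slope $b = \log\frac{1-p_1}{1-p_0}\big/D$ with
$D = \log\frac{p_0}{p_1} + \log\frac{1-p_1}{1-p_0}$, and intercepts
$h_a = \log\frac{1-\beta}{\alpha}/D$, $h_r = -\log\frac{1-\alpha}{\beta}/D$.
Sampling is truncated at `max_seeds` (default 200, one conventional
fixed-test size), where the observed proportion is compared with the
midpoint $(p_0+p_1)/2$ — truncation therefore never returns
"continue". Defaults ($p_0$ = standard + 0.05, $p_1$ = standard − 0.10,
$\alpha = \beta = 0.05$, batches of 40) are this package's documented
choices, not a reproduction of any published scheme's tables; users
holding published boundary tables can check them against
`sprt_boundaries()` directly. Simulated operating characteristics
confirm the nominal risks, and the seed saving is largest exactly where
genebanks live — lots whose viability is still well above the standard
are usually accepted on the first 40-seed batch.

## Monitoring schedules

`monitoring_policy()` + `initial_interval()` encode the interval rules:
one-third of the predicted time to the absolute standard; one-third of
the time to 85% *of initial* viability; or a fixed 5- or 10-year
fallback when no prediction is possible. For the 85%-of-initial rule,
"initial" is read as the initial viability of the responding fraction
when `nonresponder_aware = TRUE`; with a 10% non-responder fraction this
nearly doubles the interval relative to naively treating the apparent
90% as true viability, which is the reading under which the rule is
coherent. (Where descriptions of this rule conflict — "one-third of
initial" versus "85% of initial" — the latter is implemented; the
former appears to be an erratum.)

`update_after_result()` deliberately does *not* re-predict the schedule
after every test: with realistic test error, literal re-prediction makes
intervals lengthen as well as shorten and wastes seed. Instead a result
at or below the standard triggers regeneration; a result in a narrow
warning band just above it (default 2 points, i.e. 86–87% against an
85% standard — the band in which retrospective transition data show a
roughly even chance the lot is effectively at the standard) halves the
interval; higher results keep or shorten the interval but can never
lengthen it past its initial value. The warning-band width is a
documented design choice, not an estimated quantity. `batch_schedule()`
implements longevity-ranked batch testing: only the shortest-lived
quantile of lots is dated for testing; later batches carry an
event flag (`awaiting_batch`) and start only when the previous batch
begins to reach the standard.

## The simulator, and what passing tests do and do not show

`simulate_test()`, `simulate_storage_experiment()`, `simulate_cohort()`
and `simulate_history()` generate data with known truth. Replicates are
binomial by default; an overdispersion knob (beta-binomial intra-class
correlation) emulates scorer bias and environment gradients. Cohort
defaults — $K_i \sim N(2.5, 0.4)$ probits,
$\sigma \sim \text{logNormal}(\log 10^4, 0.6)$ days, i.e. a median of
about 27 years per probit — were chosen once so that roughly a tenth of
lots cross an 85% standard within a 20-year horizon: enough crossings to
exercise every scheduler branch without making decline the norm. All
randomness flows through explicit seeds in locally scoped RNG state, so
every fixture is reproducible and no call disturbs the caller's random
stream.

The simulator draws exactly the model the estimators assume (probit
survival, binomial sampling). Parameter-recovery and coverage results on
simulated data therefore validate the *implementation*, not the model:
they cannot detect survival curves that are non-probit in time, drifting
storage conditions, dormancy, or scorer artefacts in real collections.
The overdispersion knob probes robustness to one such violation only.

Test and validation problem sizes (storage-experiment grids of 6–10
days at 25–200 seeds; 300–500 simulation replicates; 20-lot ranking
cohorts; 200-lot, 20-year policy runs) were chosen as the smallest
designs at which the Monte-Carlo error is comfortably below the effect
being checked.

## Numerical choices, in brief

* Percent–probit conversions refuse 0 and 100% (infinite probits).
* Pooled test percentages are $\sum x_i / \sum n_i$, never the mean of
  replicate percentages (replicates may differ in $n$).
* Transition summaries round percentages half-up to integers and match
  test pairs on whole elapsed years.
* Ranking ties break by lot id; lots whose initial viability is below
  the target percentile rank first with time 0.
* Years convert to days at 365.25 throughout.
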