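---
title: "Standardized mean differences without the equal-variance assumption"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standardized mean differences without the equal-variance assumption}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smde)
```

## The problem

A standardized mean difference (SMD) divides a mean difference by an SD-scale
quantity so that effects are unit-free and comparable across studies — the
bread and butter of meta-analysis and power analysis. The classical
two-sample SMDs, Cohen's $g$ and its bias-corrected form Hedges'
$d = J(n_1+n_2-2)\,g$, standardize by the *pooled* SD and therefore assume
the two populations share one variance. That assumption is routinely
violated in practice, and when it fails $g$ and $d$ stop estimating the
parameter $\delta = (\mu_1-\mu_2)/\sigma$: they drift toward a
sample-size-dependent target (see `delta_q_param()`), so two studies with
different group sizes are no longer estimating the same thing.

This package implements a Welch-based SMD that drops the equal-variance
assumption. Its population parameter is

$$\epsilon_r = \frac{\mu_1-\mu_2}{\sqrt{(\sigma_1^2 + r\,\sigma_2^2)/(r+1)}},
\qquad r = n_1/n_2,$$

and its unbiased estimator is built from Welch's $t$:

$$e = \frac{t_w}{\sqrt{\tilde n}}\,J(f), \qquad
t_w = \frac{\bar Y_1 - \bar Y_2}{\sqrt{s_1^2/n_1 + s_2^2/n_2}}, \qquad
\tilde n = \frac{n_1 n_2}{n_1+n_2},$$

with $f$ the (fractional) Welch–Satterthwaite degrees of freedom. The same
correction machinery yields an unbiased one-sample effect size
$c = J(n_1-1)\,(\bar Y_1 - C)/s_1$ for comparing a mean against a known
constant $C$ (a physical constant, an optimum, a null value for paired
differences). Glass' $\Delta$ and Bonett's $\hat\delta$ are included for
comparison.

## The bias correction $J(m)$

Every estimator here is, after scaling, a noncentral-$t$ variate, and the
expectation of such a variate overshoots its noncentral parameter by the
factor $1/J(m)$ with

$$J(m) = \frac{\Gamma(m/2)}{\sqrt{m/2}\;\Gamma((m-1)/2)}.$$

`correction_j()` evaluates this in log space
(`exp(lgamma(m/2) - lgamma((m-1)/2) - log(m/2)/2)`): the gamma function
itself overflows double precision near $m \approx 343$, while the log-gamma
ratio is stable at any df, so the exact coefficient is available at every
fractional $f$. Above $m = 342$ the code switches to the classical
approximation $1 - 3/(4m-1)$; at that point the two branches agree to
better than $10^{-5}$, so the switch is numerically invisible. $J$ is kept
at the *fractional* Welch df throughout — rounding $f$ to an integer
changes the corrected estimate in the third decimal for small samples,
which is visible at the precision this package reports.

## Variances and plug-in convention

The sampling variance of $e$ is

$$\mathrm{var}(e) = \frac{f}{f-2}J^2(f)\left(\frac{1}{\tilde n} +
\epsilon_r^2\right) - \epsilon_r^2,$$

with the analogous $m = n_1+n_2-2$ form for $d$ and the $\nu = n_1-1$ form
for $c$. Since the parameter is unknown, a plug-in estimate takes its
place; this package always plugs in the **biased** point estimate ($g$,
$e_\mathrm{biased}$, $c_\mathrm{biased}$), never the corrected one. For
the variance of an *uncorrected* statistic the same second-moment algebra
gives $\frac{\nu}{\nu-2}(1/k+\theta^2) - \theta^2/J^2(\nu)$, because the
uncorrected estimator's mean is $\theta/J$. The one-sample formulas use
the $\nu = n_1 - 1$ scaling of the pivot $t = (\bar Y - C)\big/\sqrt{s^2/(n_1-1)}$,
which is the convention the rest of the one-sample machinery (variance and
CI alike) follows consistently.

## Confidence intervals

No closed form exists for the CI of a noncentral-$t$ effect size. The CDF
of the noncentral $t$ at a fixed quantile is strictly decreasing in the
noncentral parameter, so `find_ncp()` inverts it by monotone bisection:
bracket the root by geometric expansion from $[t_{obs}-1,\,t_{obs}+1]$
(up to 60 doublings), then bisect to an absolute tolerance of $10^{-8}$ on
the ncp. The interval on the effect-size scale is
$[\mathrm{ncp}_L, \mathrm{ncp}_H]/\sqrt{\tilde n}$ (or $/\sqrt{n_1-1}$ for
the one-sample family), multiplied elementwise by $J$ for the corrected
estimators. The search is vectorized over replicates — one `pt()` call per
bisection step services an entire Monte Carlo column — which is what makes
simulating mean CI widths over tens of thousands of replicates cheap.

Numerical notes:

* the returned root satisfies $|F(t_{obs}; f, \mathrm{ncp}) - p| < 10^{-6}$
  when re-evaluated;
* `stats::pt()` accepts non-integer df, which the `e` family requires;
* degenerate inputs (zero variance in both groups, $n \le$ the df floor of
  a variance formula) are errors, not silent `NA`s.

Tunable parameters, all through `ncp_search_config()` or the top-level
functions: `alpha` (two-sided type-I error of the interval, default 0.05),
`tol` (ncp tolerance, default `1e-8`), `max_expand` (bracket doublings,
default 60). `unbiased = FALSE` switches estimate, variance and CI to the
uncorrected statistic together.

## The Monte Carlo harness

`simulation_spec()` / `run_cell()` / `run_grid()` draw `reps` independent
pairs of samples from $N(\mu_1, \sigma_1^2)$ and $N(\mu_2, \sigma_2^2)$ and
average $d$, $e$, Bonett's $\hat\delta$ and the corrected 95% CI widths of
$d$ and $e$. The defaults emulate the standard design for studying SMD
bias under heteroscedasticity: $\mu = (1, 0)$, $\sigma_1 = 1$, group sizes
10–30, $\sigma_2$ up to 10 (`table3_specs()` builds the full 36-cell grid).
`reps` defaults to 20,000, which puts the Monte Carlo standard error of an
averaged point estimate below about 0.005 — tight enough to see every
effect the grid is designed to show while the whole grid runs in a couple
of minutes on one core; raise `reps` for publication-grade tables.

Design choices worth knowing:

* each cell runs on its own RNG stream (`seed + cell index`), so any cell
  is reproducible in isolation;
* Bonett's $\hat\delta$ has no exact noncentral-$t$ df; following its
  pooled-df behavior the harness reports it with the $J(n_1+n_2-2)$
  correction, which makes the column coincide with $d$ replicate-wise
  whenever $n_1 = n_2$ (the raw statistic is available as
  `bonett_delta_hat()`);
* Bonett's own approximate CI is a different construction (not a
  noncentral-$t$ inversion) and is deliberately not produced; the formatted
  grid prints `N.A.` in that column and `U.D.` for his undefined parameter;
* replicates with a zero within-group variance are redrawn — impossible
  for continuous draws, but it keeps degenerate user specs from crashing.

What the generator does *not* emulate: non-normal populations, correlated
groups, contamination/outliers, or unequal-variance mechanisms beyond a
fixed $\sigma_2/\sigma_1$ ratio. A passing grid therefore demonstrates the
estimators' behavior under exactly the normal-theory conditions they were
derived for, not robustness beyond them.

```{r sim, eval = FALSE}
grid <- run_grid(table3_specs(reps = 20000, seed = 1))
format_grid(grid)
```

## Worked example

```{r worked}
data1 <- c(0, 1, 2, 3, 4)
data2 <- c(0, 0, 1, 2, 2)
es_d(data1, data2)
es_e(data1, data2)
es_c(data2, 2, alpha = 0.01, unbiased = FALSE)
```

The sample SDs differ by a factor `r round(sqrt(2.5), 2)`, so $d$ and $e$
already separate in the third decimal at $n = 5$ per group. On real data
the practical diagnostic is the SD ratio: `species_contrast_table()` runs
all pairwise species contrasts on Fisher's (1936) iris measurements
(bundled as `iris_measurements()`; note these are Fisher's original
values, which differ from R's `datasets::iris` in three *I. setosa* cells)
and reports $d$, $e$, $d/e$ and the SD ratio — the further the SD ratio is
from 1, the further $d$ drifts from $e$.

```{r iris}
head(species_contrast_table(), 3)
```

## Known limitations

* When both the variances *and* the sample-size ratio differ across
  studies, $\epsilon_r$ itself differs across studies; no SMD fixes this
  (it is a facet of the Behrens–Fisher problem). $e$ is comparable across
  studies only at a common $r$.
* $E(e) = \epsilon_r$ treats the Welch df $f$ as fixed, but $f$ is itself
  estimated from the data, so exact finite-sample unbiasedness is
  approximate; empirically the residual bias is far inside Monte Carlo
  noise at $n \ge 10$ (the test suite checks recovery to 3 Monte Carlo
  SEs at 200,000 replicates).
* Printed CI endpoints from other implementations may differ in the fourth
  decimal: the endpoints depend on the ncp search granularity, and this
  implementation converges to $10^{-8}$ rather than matching any
  particular coarser grid.
* The variance of the one-sample statistic uses the $\nu = n_1-1$ scaling
  convention stated above; its distributional justification is inherited
  from the effect-size theory, not re-derived here.
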