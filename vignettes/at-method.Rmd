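---
title: "Accelerated-transition mCPR targets: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accelerated-transition mCPR targets: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpaccel)
```

## The problem

Demand-satisfied (DS) benchmarks — most prominently, 75% of the demand for
family planning among married or in-union women aged 15–49 satisfied with
modern contraceptive methods by 2030 — are stated as ratios. Programmes,
however, plan against levels: the modern contraceptive prevalence rate
(mCPR) and the number of additional users it implies. `fpaccel` converts a
DS target into a country-specific mCPR target by asking *when* the country
would reach the DS benchmark under business as usual (BAU), and what mCPR it
would have then.

## Indicator definitions

For a population of married or in-union women of reproductive age (MWRA), a
*prevalence state* is the triple (modern use, traditional use, unmet need),
all proportions with a non-negative sum at most 1. Derived indicators:

* **total demand** = modern + traditional + unmet;
* **demand satisfied (DS)** = modern / total demand.

All computation is done on the proportion scale; files and reports use the
percent scale, converted exactly at the boundary (`pct_to_prop`,
`prop_to_pct`). Two conventions: DS is defined as 0 when total demand is 0
(the case never arises on projected trajectories with positive prevalence,
but a documented convention beats undefined behaviour), and state validation
tolerates a sum of 1 + 1e-9 to absorb floating-point accumulation.

## The transition model

The BAU engine is a deliberately simple, deterministic stand-in for the
Bayesian hierarchical machinery used in production estimation systems. It
keeps the structural ideas — a logistic contraceptive-use transition and an
explicit link between prevalence and unmet need — while remaining fully
testable at desk scale. Three curves, seven parameters:

* **Total prevalence**: logistic in time,
  $P(t) = P_{\max} / (1 + e^{-\omega (t - \Omega)})$, with asymptote
  $P_{\max} \in (0, 0.95]$, rate $\omega \in (0, 1]$ per year and midpoint
  year $\Omega \in [1950, 2150]$. Use starts slow, speeds up, then slows as
  high prevalence is reached.
* **Modern share**: the modern fraction of total prevalence is logistic in
  time, $s(t) = \mathrm{expit}(a_s + b_s (t - \Omega))$. Modern use is
  $s(t) P(t)$, traditional use $(1 - s(t)) P(t)$. A share logistic in $P$
  rather than $t$ would be equally defensible; time was chosen because
  method mix keeps modernising in observed series even where total
  prevalence has plateaued.
* **Unmet need**: a log-odds-linear fraction of non-users,
  $U(t) = (1 - P(t))\,\mathrm{expit}(a_u + b_u P(t))$. This parameterisation
  structurally guarantees $P + U \le 1$, so every model state is a valid
  prevalence state by construction — no clipping anywhere downstream. With
  $b_u < 0$, unmet need first rises with demand and then falls as use
  displaces it, the shape seen in survey compilations.

### Fitting

`fit_fp_transition()` minimises a penalised weighted least-squares objective
on the log-odds scale of the three observed quantities (total prevalence,
modern share, unmet fraction of non-users). Weights are proportional to
$1/\mathrm{sd}^2$ where a sampling standard deviation is supplied, equal
otherwise, and normalised to mean 1. Observed proportions are clamped to
$[10^{-6}, 1 - 10^{-6}]$ before the log-odds transform; a residual whose
observed component is undefined (zero total prevalence, or prevalence of 1)
is dropped rather than fabricated.

A quadratic penalty $\lambda \sum_j ((\theta_j - c_j)/s_j)^2$ pulls four
parameters toward defaults: $P_{\max} \to 0.85$ (scale 0.15),
$\omega \to 0.07$/yr (scale 0.05), $b_s \to 0.05$/yr (scale 0.10) and
$b_u \to -1$ (scale 2). The penalty plays the role hierarchical shrinkage
plays in multi-country models: with a single observation it pins those four
parameters at their centres while the midpoint and the two intercepts (never
penalised) position the curves through the data; with a well-observed series
its influence is negligible. The default weight $\lambda = 10^{-4}$ was
chosen so that a noise-free eight-point series recovers all seven parameters
to better than 0.1% relative error while sparse fits remain identified.

Optimisation is bounded quasi-Newton (`L-BFGS-B`, `factr = 100`,
`pgtol = 1e-10`, numerical gradients with step `1e-7`, per-parameter
scaling) from a deterministic starting point: penalised parameters at their
centres, the midpoint seeded by solving the logistic through the latest
observation, intercepts from data means. No multistart is attempted:
determinism (two runs on identical input give bit-identical parameters) was
preferred over global-optimality guarantees, and the start is documented so
the trade-off is inspectable. Non-convergence raises an error carrying the
optimiser diagnostics — never a silent fallback. Uncertainty intervals are
out of the core path; `simulate()` on a fitted model supports a parametric
bootstrap if one is wanted.

## The AT and DB measures

With baseline year $t_{cur}$ (default 2019), goal year 2030 and cap 2100:

* $t^*$ = first *integer grid* year at or after $t_{cur}$ with DS at or
  above the target, capped at 2100 (`capped` flag). Trajectories live on an
  annual integer grid because assessments report integer years; whether a
  production system would evaluate mid-year is unknowable from published
  tables, so the grid convention is ours, and the fine-grid scan used as a
  test oracle confirms the integer answer is the ceiling of the continuous
  crossing for monotone DS series.
* relative acceleration $= (t^* - t_{cur}) / (2030 - t_{cur})$, kept
  unrounded internally; reports round to one decimal, *half away from zero*
  (base R rounds half to even, which disagrees with published tables on
  exact halves).
* AT target mCPR $=$ BAU mCPR at $t^*$; mCPR gap $=$ target minus baseline
  mCPR; users gap $=$ gap $\times$ MWRA. Countries already on track get
  gaps reported as 0 with an explicit flag rather than negative values,
  which published tables omit rather than print.
* The baseline year default of 2019 is the value consistent with every
  published acceleration we recompute (e.g. a 2054 target year yielding
  35/11 ≈ 3.2); it is exposed in `at_config()`, not hard-coded.
* The accelerated trajectory maps year $t$ in $[t_{cur}, 2030]$ to the BAU
  state at $t_{cur} + \mathrm{rel.accel}\,(t - t_{cur})$ (linear
  interpolation between grid years), so the accelerated path reaches the
  $t^*$ state — and hence the DS target — exactly in the goal year, and
  every accelerated state is a BAU state at some time: the mCPR–demand
  relationship is preserved pointwise. Beyond 2030 the path continues as
  BAU shifted by $t^* - 2030$; published figures stop at 2030, so the
  continuation is a documented extension.
* The DB comparator sets the target to DS-target × BAU demand in 2030. Its
  gap uses the same baseline mCPR as the AT gap, so AT−DB differences
  isolate the target definition. Under non-decreasing demand and
  $t^* > 2030$, demand at $t^*$ is at least demand at 2030, so the AT
  target dominates the DB target; with constant demand they coincide — both
  facts are tested exactly.

The packaged 50-row DS75 assessment table ships with an md5 integrity check.
Its final column reproduces the source's demand-based column verbatim and is
never interpreted by computation: the published header calls it a gap, but
its values track the DB *target* closely, and the ambiguity cannot be
resolved from the table alone.

## The synthetic-data generator

`synth_country()` / `generate_observations()` emulate the sparse national
survey record the assessment is normally run on: 8 observation years within
1968–2019, independent Gaussian noise of sd 0.02 added on the log-odds scale
to each of total prevalence, modern share and unmet fraction (roughly the
sampling error of a large household survey), components then rebuilt so
every observation is a valid state without clipping. `generate_panel()`
draws ground-truth parameters from documented uniform ranges per scenario:
`mixed` (broad ranges spanning on-track, late and capped transitions),
`all-late` and `all-on-track` (rejection-sampled to their class), and
`capped`, whose modern-share bound (intercept at most 0.5, slope at most
0.005/yr) keeps the share below expit(1.05) < 0.75 through 2100, so the DS
benchmark is unreachable by construction. All generation is seeded
(Mersenne-Twister pinned) and restores the caller's RNG state.

What passing tests on these panels shows — and what it does not: the
generator draws from the model family the fitter assumes, with independent
noise and no source biases, so recovery results certify the estimation and
target-setting machinery, not robustness to model misspecification,
correlated survey errors, or the data-quality problems of real
compilations. Country-specific published targets and gaps depend on full
hierarchical fits to the real survey compilation and are treated as inputs
here, never as quantities this package claims to reproduce; what is
reproduced exactly is everything that is a deterministic function of
printed inputs (acceleration arithmetic, summary counts and ranges, the
users-gap identity).

## Validation problem sizes

The test suite exercises: exact indicator arithmetic; curve evaluation
against independent closed-form evaluation; fine-grid (0.001-year) brute
force for target years; noise-free recovery at n = 8 (relative error
< 1e-3); a 200-replicate Monte Carlo at n = 8, sd = 0.02 (median absolute
asymptote error < 0.05); bias shrinkage as noise decreases (sd 0.02 vs
0.001, 30 replicates each); AT-vs-DB dominance over a 68-country mixed
panel; and a 20-country panel for the rank correlation between the AT−DB
gap difference and the required acceleration. These sizes keep the full
suite in the tens of seconds while leaving the Monte-Carlo bounds
comfortably away from their thresholds.

## Known limitations

* The transition model is a single-country approximation: no borrowing of
  strength across countries beyond the fixed penalty, no time-correlated
  distortions, no survey-source bias terms, no all-women denominators.
* Equivalence with any production estimation system's posterior
  trajectories is explicitly not claimed; the AT construction itself is
  agnostic to how the BAU trajectory was produced, and accepts any
  trajectory on the annual grid.
* The fitter's objective is non-convex; the documented deterministic start
  has proven adequate across the tested scenario ranges, but pathological
  series could converge to local optima (the error-on-non-convergence
  policy surfaces only optimiser failure, not local optimality).
* Accelerations are assessed on DS for married or in-union women only, the
  population for which the benchmark is defined.
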