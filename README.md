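# fpaccel

Tools for turning demand-satisfied (DS) benchmarks for family planning into
actionable modern-contraceptive-prevalence (mCPR) targets.

A widely used benchmark tied to SDG indicator 3.7.1 asks that at least 75% of
the demand for family planning among married or in-union women aged 15–49 be
satisfied with modern contraceptive methods (DS75) in every country by 2030.
A DS target is a ratio, not a prevalence level, so programme planners need a
translation into the mCPR level a country must reach. `fpaccel` implements
the **accelerated-transition (AT) method** for that translation, together
with the **demand-based (DB) comparator**, a simplified one-country
transition projection model that supplies the business-as-usual (BAU)
trajectories both methods operate on, and a synthetic-survey generator with
known ground truth for validation.

## The methods

Let `ds(t)` be projected demand satisfied under BAU, `mod(t)` projected mCPR,
and `t_cur` the baseline year (default 2019). With goal year 2030 and a
search cap at 2100:

- **t\*** — the earliest year with `ds(t) ≥ 0.75`, capped at 2100. If the cap
  binds, the 2100 state is used and the country is flagged `capped`.
- **Relative acceleration** — `rel.accel = (t* − t_cur) / (2030 − t_cur)`:
  the factor by which the contraceptive-use transition must speed up to hit
  the DS target on time. A value of 2 means "twice as fast".
- **AT target mCPR** — `tmod = mod(t*)`: the mCPR associated with reaching
  the DS target becomes the 2030 target.
- **mCPR gap** — `tmod − mod(t_cur)`, in percentage points; multiplied by the
  number of married or in-union women of reproductive age (MWRA) it gives the
  additional modern-method users required.
- **Accelerated trajectory** — BAU with time rescaled by `rel.accel` between
  the baseline and goal years, so the whole transition (prevalence *and*
  demand) reaches the `t*` state in 2030; after 2030 it continues as
  time-shifted BAU.
- **DB target** (comparator) — `0.75 × demand(2030)` under BAU: it
  accelerates modern use only, holding demand fixed, and is therefore never
  above the AT target when demand is rising.

The BAU engine is a deterministic stand-in for full Bayesian prevalence
estimation: total prevalence follows a logistic growth curve, the modern
share of use is logistic in time, and unmet need is modelled as a fraction of
non-users, fitted to sparse survey series by penalised nonlinear least
squares. See the methods vignette (`vignettes/at-method.Rmd`) for the model,
its assumptions and its limitations.

## Worked example

```r
library(fpaccel)

# A stylised late-transition country and its sparse survey record
truth <- transition_params(cpr_asymptote = 0.85, cpr_rate = 0.055,
                           cpr_midpoint = 2030, share_intercept = 0.7,
                           share_slope = 0.035, unmet_intercept = -0.8,
                           unmet_slope = -1.5)
obs <- generate_observations(synth_country(truth, seed = 21, country = "Demo"))

fit <- fit_fp_transition(obs)          # penalised logistic-transition fit
bau <- project(fit, 2019, 2100)        # annual BAU trajectory
at_assess(bau, mwra = 5e6)
```

```
AT assessment: Demo (DS target 75% by 2030)
  Target year t* = 2053
  Required acceleration: 3.1 x
  Target mCPR 50.6%, gap 33.4 percentage points
  Additional users needed: 1.67 million
```

Demand satisfied reaches 75% only in 2053 under BAU, so the transition must
run about 3.1 times faster; the mCPR projected for 2053 (50.6%) becomes the
2030 target. `db_target(bau)` prints the demand-based comparator
(`DB target for Demo: mCPR 39.0% (gap 21.9 pp)`) — lower, because it holds
demand at its 2030 level.

The packaged 50-country DS75 assessment table ships in
`inst/extdata/ds75_assessment_table.csv` (`load_table1()`), and
`summarize_results()` reproduces its headline statistics: 50 countries
needing acceleration, 35 of them by at least a factor of 3, mCPR gaps from
4.3 to 50.8 percentage points.

A command-line front end (`inst/cli/fpaccel`) wraps the same functions:
`fit`, `project`, `assess`, `simulate`, `summarize`; run it without arguments
for the flag reference.

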