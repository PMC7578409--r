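test_that("transition curves evaluate the three closed forms", {
  p <- transition_params(0.8, 0.08, 2020, 0, 0.05, -1, -2)
  st <- transition_curves(p, 2020)
  # independent evaluation via stats::plogis
  P <- 0.8 * plogis(0); s <- plogis(0)
  expect_equal(st$modern, s * P, tolerance = 1e-12)
  expect_equal(st$traditional, (1 - s) * P, tolerance = 1e-12)
  expect_equal(st$unmet, (1 - P) * plogis(-1 - 2 * P), tolerance = 1e-12)
  # logistic midpoint: total prevalence is half the asymptote
  expect_equal(st$modern + st$traditional, 0.4, tolerance = 1e-12)
  # distant past: prevalence vanishes, unmet tends to expit(intercept)
  early <- transition_curves(p, 1700)
  expect_lt(early$modern + early$traditional, 1e-9)
  expect_equal(early$unmet, plogis(-1), tolerance = 1e-6)
})

test_that("curve states always satisfy the prevalence invariants", {
  set.seed(7)
  for (i in 1:100) {
    p <- transition_params(runif(1, 0.05, 0.95), runif(1, 0.01, 1),
                           runif(1, 1950, 2150), runif(1, -3, 3),
                           runif(1, -0.2, 0.2), runif(1, -3, 3),
                           runif(1, -5, 5))
    st <- transition_curves(p, seq(1950, 2150, by = 10))
    expect_silent(validate_state(st))
    P <- st$modern + st$traditional
    expect_true(all(st$modern >= 0 & st$modern <= P + 1e-12))
    expect_true(all(P <= p[["cpr_asymptote"]] + 1e-12))
    expect_true(all(P + st$unmet <= 1 + 1e-12))
  }
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(transition_params(0.99, 0.07, 2000, 0, 0, 0, 0),
               "cpr_asymptote")
  expect_error(transition_params(0.8, 0, 2000, 0, 0, 0, 0), "cpr_rate")
  expect_error(transition_params(0.8, 0.07, 1900, 0, 0, 0, 0),
               "cpr_midpoint")
})

test_that("projection evaluates the curves on the annual grid", {
  traj <- project(truth_mid, 2019, 2100, country = "X")
  expect_s3_class(traj, "fp_trajectory")
  expect_equal(traj$year, 2019:2100)
  expect_equal(traj$demand, traj$modern + traj$traditional + traj$unmet,
               tolerance = 1e-9)
  expect_equal(traj$ds, traj$modern / traj$demand, tolerance = 1e-9)
  # single-year projection equals pointwise curve evaluation
  one <- project(truth_mid, 2030, 2030)
  st <- transition_curves(truth_mid, 2030)
  expect_equal(one$modern, st$modern)
  # rising share and prevalence make modern use non-decreasing
  expect_true(all(diff(traj$modern) >= 0))
  expect_error(project(truth_mid, 2030, 2020), "y_start")
})

test_that("ds trajectories with rising share and falling unmet are monotone", {
  set.seed(11)
  for (i in 1:25) {
    p <- transition_params(runif(1, 0.5, 0.95), runif(1, 0.02, 0.3),
                           runif(1, 1980, 2080), runif(1, -1, 1),
                           runif(1, 0, 0.1), runif(1, -2, 0),
                           runif(1, -4, 0))
    traj <- project(p, 2019, 2100)
    expect_true(all(diff(traj$ds) >= -1e-12))
  }
})

test_that("noise-free surveys recover the generating parameters", {
  fit <- fit_fp_transition(noise_free_obs(truth_mid))
  rel_err <- abs((unclass(coef(fit)) - unclass(truth_mid)) /
                   unclass(truth_mid))
  expect_lt(max(rel_err), 1e-3)
})

test_that("a single observation yields the penalty-dominated analytic fit", {
  st <- transition_curves(truth_mid, 2000)
  one <- data.frame(year = 2000, modern = st$modern,
                    traditional = st$traditional, unmet = st$unmet)
  fit <- fit_fp_transition(one)
  par <- coef(fit)
  # analytic solution: penalised parameters at their centres, the free
  # parameters solving the single observation exactly
  P <- one$modern + one$traditional
  omega <- 2000 + log(0.85 / P - 1) / 0.07
  share_int <- logit_(one$modern / P) - 0.05 * (2000 - omega)
  unmet_int <- logit_(one$unmet / (1 - P)) + P
  expect_equal(par[["cpr_asymptote"]], 0.85, tolerance = 1e-4)
  expect_equal(par[["cpr_rate"]], 0.07, tolerance = 1e-4)
  expect_equal(par[["share_slope"]], 0.05, tolerance = 5e-3)
  expect_equal(par[["unmet_slope"]], -1, tolerance = 5e-3)
  expect_equal(par[["cpr_midpoint"]], omega, tolerance = 1e-2)
  expect_equal(par[["share_intercept"]], share_int, tolerance = 1e-2)
  expect_equal(par[["unmet_intercept"]], unmet_int, tolerance = 1e-2)
})

test_that("fitting is deterministic: identical inputs, identical parameters", {
  obs <- generate_observations(synth_country(truth_mid, seed = 5))
  f1 <- fit_fp_transition(obs)
  f2 <- fit_fp_transition(obs)
  expect_identical(unclass(coef(f1)), unclass(coef(f2)))
})

test_that("observation weights follow the sampling standard deviations", {
  obs <- noise_free_obs(truth_mid)
  obs$modern[1] <- min(obs$modern[1] + 0.3, 0.6)  # corrupt one observation
  obs$obs_sd <- c(10, rep(0.005, nrow(obs) - 1))  # ...and downweight it
  fit_w <- fit_fp_transition(obs)
  obs$obs_sd <- NULL
  fit_u <- fit_fp_transition(obs)
  truth_vec <- unclass(truth_mid)
  err_w <- max(abs(unclass(coef(fit_w)) - truth_vec))
  err_u <- max(abs(unclass(coef(fit_u)) - truth_vec))
  expect_lt(err_w, err_u)
  expect_lt(err_w, 0.05)
})

test_that("parameter bias shrinks as survey noise shrinks", {
  mae <- sapply(c(0.02, 0.001), function(sd) {
    errs <- sapply(1:30, function(s) {
      obs <- generate_observations(synth_country(truth_mid, noise_sd = sd,
                                                 seed = s))
      max(abs(unclass(coef(fit_fp_transition(obs))) - unclass(truth_mid)) /
            abs(unclass(truth_mid)))
    })
    median(errs)
  })
  expect_lt(mae[2], mae[1])
  expect_lt(mae[2], 0.01)
})

test_that("fit errors are informative", {
  expect_error(fit_fp_transition(data.frame()), "at least one observation")
  expect_error(fit_fp_transition(data.frame(year = 2000, modern = 0.2)),
               "column")
  expect_error(fit_fp_transition(
    data.frame(year = 1900, modern = 0.1, traditional = 0.1, unmet = 0.1)),
    "1950")
})

test_that("model methods are coherent with the fitted parameters", {
  obs <- generate_observations(synth_country(truth_mid, seed = 3))
  fit <- fit_fp_transition(obs)
  expect_equal(unname(fitted(fit)$modern),
               unname(transition_curves(coef(fit), obs$year)$modern))
  r <- residuals(fit)
  expect_equal(dim(r), c(nrow(obs), 3))
  expect_lt(max(abs(r)), 0.2)  # log-odds noise sd 0.02: residuals are small
  pr <- predict(fit, 2019:2100, type = "trajectory")
  expect_s3_class(pr, "fp_trajectory")
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_silent(validate_state(sims[[1]]))
  expect_output(print(summary(fit)), "RMSE")
})
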