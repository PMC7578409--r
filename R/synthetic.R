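# Run code under a fixed seed, restoring the caller's RNG state afterwards.
# Mersenne-Twister is pinned so cross-run results are reproducible even if
# the session default ever changes.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed, kind = "Mersenne-Twister")
  force(code)
}

#' Specification of a synthetic survey country
#'
#' Bundles the ground-truth transition parameters with the survey design used
#' to emulate a sparse national survey series: by default eight observation
#' years spanning 1968-2019, matching the density of the historical
#' compilations the assessment is normally run on.
#'
#' @param truth A \code{\link{transition_params}} vector: the data-generating
#'   parameters.
#' @param survey_years Observation years (default 8 evenly spaced years over
#'   1968-2019).
#' @param noise_sd Standard deviation of the independent Gaussian survey noise
#'   added on the log-odds scale to each of total prevalence, modern share and
#'   unmet fraction of non-users. The default 0.02 resembles the sampling
#'   error of a large household survey.
#' @param mwra Married or in-union women of reproductive age (population
#'   denominator for user counts).
#' @param country Identifier.
#' @param seed Integer seed making observation generation deterministic.
#' @return A list of class \code{"synth_country"}.
#' @export
synth_country <- function(truth,
                          survey_years = round(seq(1968, 2019, length.out = 8)),
                          noise_sd = 0.02, mwra = 1e6,
                          country = "synthetic", seed = 1L) {
  validate_params(truth)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(truth = truth, survey_years = survey_years,
                 noise_sd = noise_sd, mwra = mwra,
                 country = as.character(country), seed = as.integer(seed)),
            class = "synth_country")
}

#' Generate noisy survey observations from a synthetic country
#'
#' Evaluates the true transition curves at each survey year, perturbs total
#' prevalence, modern share and unmet fraction of non-users with independent
#' Gaussian noise on the log-odds scale, and reconstructs the component
#' proportions. Because the components are rebuilt from bounded quantities
#' (share and unmet fraction via the inverse log-odds), every generated
#' observation satisfies the prevalence-state invariants. Deterministic given
#' the seed.
#'
#' @param spec A \code{\link{synth_country}}.
#' @return A data frame of survey observations with columns \code{country},
#'   \code{year}, \code{modern}, \code{traditional}, \code{unmet},
#'   \code{obs_sd} (NA: the noise is on the log-odds scale).
#' @export
generate_observations <- function(spec) {
  stopifnot(inherits(spec, "synth_country"))
  yrs <- spec$survey_years
  truth <- spec$truth
  st <- transition_curves(truth, yrs)
  P <- st$modern + st$traditional
  share <- ifelse(P > 0, st$modern / P, 0.5)
  uf <- ifelse(P < 1, st$unmet / (1 - P), 0.5)
  with_seed(spec$seed, {
    zP <- logit(clamp01(P)) + stats::rnorm(length(yrs), 0, spec$noise_sd)
    zs <- logit(clamp01(share)) + stats::rnorm(length(yrs), 0, spec$noise_sd)
    zu <- logit(clamp01(uf)) + stats::rnorm(length(yrs), 0, spec$noise_sd)
    P2 <- expit(zP); s2 <- expit(zs); u2 <- (1 - P2) * expit(zu)
    data.frame(country = spec$country, year = yrs,
               modern = s2 * P2, traditional = (1 - s2) * P2, unmet = u2,
               obs_sd = NA_real_)
  })
}

.PANEL_SCENARIOS <- c("mixed", "all-late", "all-on-track", "capped")

runifn <- function(n, lo, hi) stats::runif(n, lo, hi)

draw_mixed_truth <- function() {
  transition_params(
    cpr_asymptote = runifn(1, 0.60, 0.90),
    cpr_rate = runifn(1, 0.04, 0.12),
    cpr_midpoint = runifn(1, 1990, 2060),
    share_intercept = runifn(1, -0.5, 1.0),
    share_slope = runifn(1, 0.01, 0.08),
    unmet_intercept = runifn(1, -1.5, -0.5),
    unmet_slope = runifn(1, -3, -0.5))
}

# Modern share stays below expit(0.5 + 0.005 * 110) < 0.75 through 2100, so
# demand satisfied can never reach the DS75 benchmark: capped by construction.
draw_capped_truth <- function() {
  transition_params(
    cpr_asymptote = runifn(1, 0.60, 0.85),
    cpr_rate = runifn(1, 0.04, 0.10),
    cpr_midpoint = runifn(1, 1990, 2040),
    share_intercept = runifn(1, -0.5, 0.5),
    share_slope = runifn(1, 0, 0.005),
    unmet_intercept = runifn(1, -1.0, -0.3),
    unmet_slope = runifn(1, -1, 0))
}

draw_on_track_truth <- function() {
  transition_params(
    cpr_asymptote = runifn(1, 0.70, 0.90),
    cpr_rate = runifn(1, 0.07, 0.12),
    cpr_midpoint = runifn(1, 1975, 1995),
    share_intercept = runifn(1, 1.5, 3.0),
    share_slope = runifn(1, 0.02, 0.08),
    unmet_intercept = runifn(1, -2.5, -1.5),
    unmet_slope = runifn(1, -3, -1))
}

#' Generate a panel of synthetic countries
#'
#' Draws ground-truth transition parameters from documented uniform ranges for
#' each of \code{n_countries} countries. Scenarios constrain where the
#' demand-satisfied benchmark is crossed under business as usual:
#' \describe{
#'   \item{mixed}{broad ranges producing on-track, accelerating and capped
#'     countries together;}
#'   \item{all-late}{every country crosses the benchmark after the goal year
#'     but by the cap year (rejection-sampled from the mixed ranges);}
#'   \item{all-on-track}{every country meets the benchmark by the goal year
#'     (early, fast transitions; rejection-sampled);}
#'   \item{capped}{the modern share is bounded below the benchmark through the
#'     cap year, so no country ever reaches it.}
#' }
#' Deterministic given the seed. Survey years are 8 draws without replacement
#' from 1968-2019; population denominators are log-uniform between 3e5 and
#' 3e7 women.
#'
#' @param n_countries Number of countries.
#' @param seed Integer seed.
#' @param scenario One of \code{"mixed"}, \code{"all-late"},
#'   \code{"all-on-track"}, \code{"capped"}.
#' @param config An \code{\link{at_config}} used by the rejection-sampled
#'   scenarios.
#' @return A list of \code{\link{synth_country}} specifications, named by
#'   country id (\code{C01}, \code{C02}, ...).
#' @export
generate_panel <- function(n_countries, seed = 1L, scenario = "mixed",
                           config = at_config()) {
  if (!scenario %in% .PANEL_SCENARIOS)
    stop("unknown scenario '", scenario, "'; available: ",
         paste(.PANEL_SCENARIOS, collapse = ", "), call. = FALSE)
  crossing_class <- function(truth) {
    traj <- project(truth, config$current_year, config$cap_year)
    ty <- find_target_year(traj, config)
    if (ty$capped) "capped"
    else if (ty$t_star <= config$goal_year) "on-track"
    else "late"
  }
  with_seed(seed, {
    lapply(seq_len(n_countries), function(i) {
      truth <- switch(scenario,
        "mixed" = draw_mixed_truth(),
        "capped" = draw_capped_truth(),
        "all-on-track" = {
          repeat {
            cand <- draw_on_track_truth()
            if (crossing_class(cand) == "on-track") break
          }
          cand
        },
        "all-late" = {
          repeat {
            cand <- draw_mixed_truth()
            if (crossing_class(cand) == "late") break
          }
          cand
        })
      synth_country(truth,
                    survey_years = sort(sample(1968:2019, 8)),
                    noise_sd = 0.02,
                    mwra = 10^runifn(1, log10(3e5), log10(3e7)),
                    country = sprintf("C%02d", i),
                    seed = sample.int(.Machine$integer.max, 1))
    }) |> stats::setNames(sprintf("C%02d", seq_len(n_countries)))
  })
}
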