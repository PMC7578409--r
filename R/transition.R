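expit <- function(x) 1 / (1 + exp(-x))
logit <- function(p) log(p / (1 - p))

# Clamp proportions away from {0,1} before taking log-odds.
.LOGIT_EPS <- 1e-6
clamp01 <- function(p, eps = .LOGIT_EPS) pmin(pmax(p, eps), 1 - eps)

.PAR_NAMES <- c("cpr_asymptote", "cpr_rate", "cpr_midpoint",
                "share_intercept", "share_slope",
                "unmet_intercept", "unmet_slope")

#' Parameters of the simplified contraceptive-use transition model
#'
#' The model describes one country's family-planning transition with three
#' deterministic curves:
#' \itemize{
#'   \item total contraceptive prevalence follows a logistic growth curve
#'     \eqn{P(t) = P_{max} / (1 + e^{-\omega (t - \Omega)})} with asymptote
#'     \code{cpr_asymptote} (\eqn{P_{max}}), per-year growth rate
#'     \code{cpr_rate} (\eqn{\omega}) and midpoint year \code{cpr_midpoint}
#'     (\eqn{\Omega});
#'   \item the modern share of total prevalence is logistic in time,
#'     \eqn{s(t) = \mathrm{expit}(a_s + b_s (t - \Omega))}, so modern use is
#'     \eqn{s(t) P(t)} and traditional use is \eqn{(1 - s(t)) P(t)};
#'   \item unmet need is a log-odds-linear fraction of non-users,
#'     \eqn{U(t) = (1 - P(t))\,\mathrm{expit}(a_u + b_u P(t))}, which
#'     structurally guarantees prevalence plus unmet need never exceeds 1.
#' }
#'
#' @param cpr_asymptote Upper asymptote of total prevalence, in (0, 0.95].
#' @param cpr_rate Logistic growth rate per year, in (0, 1].
#' @param cpr_midpoint Calendar year at which total prevalence reaches half
#'   its asymptote, in [1950, 2150].
#' @param share_intercept,share_slope Log-odds intercept (at the midpoint
#'   year) and per-year slope of the modern share of total prevalence.
#' @param unmet_intercept,unmet_slope Log-odds intercept and slope (per unit
#'   of total prevalence) of unmet need as a fraction of non-users.
#' @return A named numeric vector of class \code{"transition_params"}.
#' @examples
#' pars <- transition_params(0.8, 0.08, 2020, 0, 0.05, -1, -2)
#' transition_curves(pars, 2020)
#' @export
transition_params <- function(cpr_asymptote, cpr_rate, cpr_midpoint,
                              share_intercept, share_slope,
                              unmet_intercept, unmet_slope) {
  p <- c(cpr_asymptote = cpr_asymptote, cpr_rate = cpr_rate,
         cpr_midpoint = cpr_midpoint, share_intercept = share_intercept,
         share_slope = share_slope, unmet_intercept = unmet_intercept,
         unmet_slope = unmet_slope)
  class(p) <- "transition_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  if (!all(.PAR_NAMES %in% names(p)) || anyNA(p[.PAR_NAMES]))
    stop("transition parameters must contain finite fields ",
         paste(.PAR_NAMES, collapse = ", "), call. = FALSE)
  if (p[["cpr_asymptote"]] <= 0 || p[["cpr_asymptote"]] > 0.95)
    stop("cpr_asymptote must lie in (0, 0.95]", call. = FALSE)
  if (p[["cpr_rate"]] <= 0 || p[["cpr_rate"]] > 1)
    stop("cpr_rate must lie in (0, 1]", call. = FALSE)
  if (p[["cpr_midpoint"]] < 1950 || p[["cpr_midpoint"]] > 2150)
    stop("cpr_midpoint must lie in [1950, 2150]", call. = FALSE)
  invisible(p)
}

#' Evaluate the transition curves at given years
#'
#' Evaluates the three model curves (total prevalence, modern share, unmet
#' need; see \code{\link{transition_params}}) and returns the implied
#' prevalence state. The returned state satisfies the prevalence-state
#' invariants by construction for any valid parameters.
#'
#' @param params A \code{transition_params} object (or named vector with the
#'   same fields).
#' @param year Calendar year(s); fractional years are allowed.
#' @return A \code{\link{prevalence_state}} (vectorised over \code{year}).
#' @export
transition_curves <- function(params, year) {
  validate_params(params)
  p <- unclass(params)
  P <- p[["cpr_asymptote"]] * expit(p[["cpr_rate"]] * (year - p[["cpr_midpoint"]]))
  s <- expit(p[["share_intercept"]] + p[["share_slope"]] * (year - p[["cpr_midpoint"]]))
  u <- (1 - P) * expit(p[["unmet_intercept"]] + p[["unmet_slope"]] * P)
  prevalence_state(modern = s * P, traditional = (1 - s) * P, unmet = u)
}

#' Construct a projected annual trajectory
#'
#' A trajectory is an annual series of the five indicators for one country.
#' Demand and demand satisfied are always recomputed from the three prevalence
#' components, never stored independently.
#'
#' @param country Country identifier.
#' @param years Integer calendar-year grid.
#' @param modern,traditional,unmet Proportion series, same length as
#'   \code{years}.
#' @return A \code{data.frame} of class \code{"fp_trajectory"} with columns
#'   \code{year}, \code{modern}, \code{traditional}, \code{unmet},
#'   \code{demand}, \code{ds} and a \code{country} attribute.
#' @export
fp_trajectory <- function(country, years, modern, traditional, unmet) {
  n <- length(years)
  if (length(modern) != n || length(traditional) != n || length(unmet) != n)
    stop("all series must have the same length as 'years'", call. = FALSE)
  st <- prevalence_state(modern, traditional, unmet)
  traj <- data.frame(year = years, modern = st$modern,
                     traditional = st$traditional, unmet = st$unmet,
                     demand = total_demand(st), ds = demand_satisfied(st))
  structure(traj, country = as.character(country),
            class = c("fp_trajectory", "data.frame"))
}

#' @export
print.fp_trajectory <- function(x, ...) {
  cat("Projected trajectory for", attr(x, "country"),
      sprintf("(%d-%d)\n", min(x$year), max(x$year)))
  print.data.frame(x, ...)
  invisible(x)
}

#' Project a business-as-usual trajectory
#'
#' Evaluates the transition curves on every integer year in
#' \code{[y_start, y_end]}.
#'
#' @param params A \code{transition_params} object or a fitted
#'   \code{fp_transition} model.
#' @param y_start,y_end First and last calendar year of the grid.
#' @param country Country identifier attached to the trajectory.
#' @return An \code{\link{fp_trajectory}}.
#' @export
project <- function(params, y_start, y_end, country = "country") {
  UseMethod("project")
}

#' @export
project.default <- function(params, y_start, y_end, country = "country") {
  if (y_start > y_end) stop("y_start must not exceed y_end", call. = FALSE)
  years <- seq(floor(y_start), floor(y_end))
  st <- transition_curves(params, years)
  fp_trajectory(country, years, st$modern, st$traditional, st$unmet)
}

#' @export
project.fp_transition <- function(params, y_start, y_end,
                                  country = params$country) {
  project.default(params$par, y_start, y_end, country = country)
}

# ---- fitting ---------------------------------------------------------------

# Penalty centres and scales play the role of hierarchical shrinkage for
# data-sparse countries; see fit_fp_transition().
default_penalty <- function(weight = 1e-4) {
  list(weight = weight,
       center = c(cpr_asymptote = 0.85, cpr_rate = 0.07,
                  share_slope = 0.05, unmet_slope = -1),
       scale  = c(cpr_asymptote = 0.15, cpr_rate = 0.05,
                  share_slope = 0.10, unmet_slope = 2))
}

# Observations -> log-odds responses (total prevalence, modern share,
# unmet fraction of non-users). Rows with undefined components are dropped
# from the corresponding residual via NA.
obs_logodds <- function(obs) {
  P <- obs$modern + obs$traditional
  share <- ifelse(P > 0, obs$modern / P, NA_real_)
  uf <- ifelse(P < 1, obs$unmet / (1 - P), NA_real_)
  cbind(z_cpr = logit(clamp01(P)),
        z_share = ifelse(is.na(share), NA_real_, logit(clamp01(share))),
        z_unmet = ifelse(is.na(uf), NA_real_, logit(clamp01(uf))))
}

model_logodds <- function(par, year) {
  P <- par[["cpr_asymptote"]] * expit(par[["cpr_rate"]] * (year - par[["cpr_midpoint"]]))
  cbind(z_cpr = logit(clamp01(P)),
        z_share = par[["share_intercept"]] + par[["share_slope"]] * (year - par[["cpr_midpoint"]]),
        z_unmet = par[["unmet_intercept"]] + par[["unmet_slope"]] * P)
}

#' Fit the transition model to survey observations
#'
#' Fits the simplified transition model (see \code{\link{transition_params}})
#' to one country's survey series by penalised weighted nonlinear least
#' squares. The three observed quantities -- total prevalence, modern share of
#' total prevalence, and unmet need as a fraction of non-users -- are
#' transformed to the log-odds scale and matched to the model curves.
#' Observation weights are proportional to \code{1 / obs_sd^2} where a
#' sampling standard deviation column is supplied, and equal otherwise.
#'
#' A quadratic penalty pulls the prevalence asymptote (centre 0.85), growth
#' rate (0.07 per year), modern-share slope (0.05 per year) and unmet-need
#' slope (-1) toward documented defaults. The penalty stands in for the
#' hierarchical shrinkage a multi-country model would provide: with a single
#' observation it pins those four parameters at their centres while the
#' midpoint and intercepts adapt to pass the curves through the data, and with
#' a well-observed series its influence is negligible. The midpoint and the
#' two intercepts are never penalised.
#'
#' Optimisation uses bounded quasi-Newton (\code{L-BFGS-B}) from a
#' deterministic, documented starting point derived from the last observation;
#' no multistart is attempted, so the fit is bit-reproducible on identical
#' input. Non-convergence is an error carrying the optimiser diagnostics.
#'
#' @param observations A data frame with columns \code{year}, \code{modern},
#'   \code{traditional}, \code{unmet} (proportions) and optionally
#'   \code{obs_sd} (sampling standard deviation, proportion scale) and
#'   \code{country}.
#' @param penalty Penalty settings as produced by the default: a list with
#'   \code{weight} (overall multiplier), \code{center} and \code{scale}
#'   (named vectors over the four penalised parameters).
#' @param country Country identifier; defaults to the one in the data.
#' @param control Passed to \code{\link[stats]{optim}} after the defaults.
#' @return An object of class \code{"fp_transition"} with components
#'   \code{par} (a \code{transition_params} vector), \code{data},
#'   \code{weights}, \code{penalty}, \code{objective}, \code{convergence},
#'   \code{country} and \code{call}. Supports \code{print}, \code{summary},
#'   \code{coef}, \code{predict}, \code{fitted}, \code{residuals},
#'   \code{simulate} and \code{plot}.
#' @examples
#' truth <- transition_params(0.8, 0.08, 2000, 0, 0.05, -1, -2)
#' obs <- as.data.frame(transition_curves(truth, seq(1970, 2019, by = 7)))
#' obs$year <- seq(1970, 2019, by = 7)
#' fit <- fit_fp_transition(obs)
#' coef(fit)
#' @export
fit_fp_transition <- function(observations, penalty = default_penalty(),
                              country = NULL, control = list()) {
  obs <- as.data.frame(observations)
  if (nrow(obs) < 1) stop("at least one observation is required", call. = FALSE)
  for (col in c("year", "modern", "traditional", "unmet"))
    if (is.null(obs[[col]]))
      stop("observations must contain column '", col, "'", call. = FALSE)
  if (any(obs$year < 1950 | obs$year > 2030))
    stop("observation years must lie in [1950, 2030]", call. = FALSE)
  validate_state(obs)
  if (is.null(country))
    country <- if (!is.null(obs$country)) as.character(obs$country[1]) else "country"

  z_obs <- obs_logodds(obs)
  w <- if (!is.null(obs$obs_sd) && all(is.finite(obs$obs_sd)) &&
           all(obs$obs_sd > 0)) 1 / obs$obs_sd^2 else rep(1, nrow(obs))
  w <- w / mean(w)

  pen <- penalty
  objective <- function(theta) {
    names(theta) <- .PAR_NAMES
    z_fit <- model_logodds(theta, obs$year)
    r2 <- (z_obs - z_fit)^2
    data_term <- sum(w * rowSums(r2, na.rm = TRUE))
    pen_term <- pen$weight *
      sum(((theta[names(pen$center)] - pen$center) / pen$scale)^2)
    data_term + pen_term
  }

  # Deterministic start: asymptote/rate/slopes at penalty centres, midpoint
  # placed so the prevalence curve passes through the latest observation,
  # intercepts matched to the data means.
  i_last <- which.max(obs$year)
  P_last <- clamp01(obs$modern[i_last] + obs$traditional[i_last],
                    eps = 0.01)
  P_last <- min(P_last, 0.84)
  omega0 <- obs$year[i_last] + log(0.85 / P_last - 1) / 0.07
  omega0 <- min(max(omega0, 1950), 2150)
  P_all <- obs$modern + obs$traditional
  share0 <- logit(clamp01(mean(ifelse(P_all > 0, obs$modern / pmax(P_all, 1e-9), 0.5))))
  uf0 <- logit(clamp01(mean(obs$unmet / pmax(1 - P_all, 1e-9)))) + mean(P_all)
  start <- c(cpr_asymptote = 0.85, cpr_rate = 0.07, cpr_midpoint = omega0,
             share_intercept = share0, share_slope = 0.05,
             unmet_intercept = uf0, unmet_slope = -1)

  lower <- c(0.02, 1e-3, 1950, -10, -1, -10, -10)
  upper <- c(0.95, 1, 2150, 10, 1, 10, 10)
  ctl <- utils::modifyList(
    list(maxit = 1000, factr = 1e2, pgtol = 1e-10,
         parscale = c(0.1, 0.05, 10, 1, 0.05, 1, 1),
         ndeps = rep(1e-7, 7)),
    control)
  fit <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = lower, upper = upper, control = ctl)
  if (fit$convergence != 0)
    stop("transition fit did not converge (code ", fit$convergence, "): ",
         fit$message, call. = FALSE)
  par <- fit$par
  names(par) <- .PAR_NAMES
  class(par) <- "transition_params"
  validate_params(par)

  structure(list(par = par, data = obs, weights = w, penalty = pen,
                 objective = fit$value, convergence = fit$convergence,
                 optim_counts = fit$counts, country = country,
                 call = match.call()),
            class = "fp_transition")
}

#' @export
print.fp_transition <- function(x, ...) {
  cat("Contraceptive-use transition model for", x$country, "\n")
  cat(sprintf("  %d survey observations (%s-%s), penalised objective %.4g\n",
              nrow(x$data), min(x$data$year), max(x$data$year), x$objective))
  print(round(unclass(x$par), 4))
  invisible(x)
}

#' @export
coef.fp_transition <- function(object, ...) object$par

#' @export
fitted.fp_transition <- function(object, ...) {
  transition_curves(object$par, object$data$year)
}

#' Residuals of a fitted transition model
#'
#' @param object A fitted \code{fp_transition}.
#' @param ... Unused.
#' @return A matrix of log-odds-scale residuals (observed minus fitted) with
#'   one row per observation and columns for total prevalence, modern share
#'   and unmet fraction of non-users.
#' @export
residuals.fp_transition <- function(object, ...) {
  obs_logodds(object$data) - model_logodds(object$par, object$data$year)
}

#' Predict indicator states or trajectories from a fitted model
#'
#' @param object A fitted \code{fp_transition}.
#' @param years Calendar years at which to evaluate the curves.
#' @param type \code{"state"} returns a \code{prevalence_state};
#'   \code{"trajectory"} returns an annual \code{\link{fp_trajectory}}
#'   spanning \code{range(years)}.
#' @param ... Unused.
#' @export
predict.fp_transition <- function(object, years = 2019:2100,
                                  type = c("state", "trajectory"), ...) {
  type <- match.arg(type)
  if (type == "state") transition_curves(object$par, years)
  else project(object$par, min(years), max(years), country = object$country)
}

#' @export
summary.fp_transition <- function(object, ...) {
  r <- residuals.fp_transition(object)
  out <- list(country = object$country, par = object$par,
              n_obs = nrow(object$data),
              rmse_logodds = sqrt(mean(r^2, na.rm = TRUE)),
              objective = object$objective)
  class(out) <- "summary.fp_transition"
  out
}

#' @export
print.summary.fp_transition <- function(x, ...) {
  cat("Transition model fit:", x$country, "\n")
  cat(sprintf("  n = %d observations; log-odds RMSE %.4f; objective %.4g\n",
              x$n_obs, x$rmse_logodds, x$objective))
  print(round(unclass(x$par), 4))
  invisible(x)
}

#' Simulate survey observations from a fitted model
#'
#' Parametric simulation: replicates the observation years of the fitted data,
#' evaluates the fitted curves there and perturbs them with the synthetic
#' survey noise model (independent Gaussian noise on the log-odds scale).
#'
#' @param object A fitted \code{fp_transition}.
#' @param nsim Number of replicate data sets.
#' @param seed Integer seed; the RNG state is restored on exit.
#' @param noise_sd Log-odds-scale noise standard deviation.
#' @param ... Unused.
#' @return A list of \code{nsim} observation data frames.
#' @export
simulate.fp_transition <- function(object, nsim = 1, seed = 1,
                                   noise_sd = 0.02, ...) {
  spec <- synth_country(truth = object$par, survey_years = object$data$year,
                        noise_sd = noise_sd, country = object$country,
                        seed = seed)
  lapply(seq_len(nsim), function(i) {
    spec$seed <- seed + i - 1L
    generate_observations(spec)
  })
}

#' Plot a fitted transition model
#'
#' Plots observed modern use, traditional use and unmet need with the fitted
#' curves; optional demand-satisfied panel line.
#'
#' @param x A fitted \code{fp_transition}.
#' @param years Year grid for the curves.
#' @param ... Passed to \code{matplot}.
#' @export
plot.fp_transition <- function(x, years = NULL, ...) {
  if (is.null(years))
    years <- seq(min(x$data$year) - 5, max(x$data$year) + 30)
  st <- transition_curves(x$par, years)
  graphics::matplot(years, cbind(st$modern, st$traditional, st$unmet),
                    type = "l", lty = 1, col = c(3, 4, 2),
                    xlab = "year", ylab = "proportion of MWRA",
                    main = paste("Transition fit:", x$country), ...)
  graphics::matpoints(x$data$year,
                      cbind(x$data$modern, x$data$traditional, x$data$unmet),
                      pch = 16, col = c(3, 4, 2))
  graphics::legend("topleft", bty = "n", lty = 1, col = c(3, 4, 2),
                   legend = c("modern", "traditional", "unmet"))
  invisible(x)
}
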