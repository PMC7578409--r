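#' Configuration for the accelerated-transition assessment
#'
#' Holds the demand-satisfied benchmark and the calendar anchors of the
#' assessment: the baseline year from which progress is measured, the goal
#' year by which the benchmark should be met, and the cap year beyond which
#' business-as-usual projections are not searched.
#'
#' @param ds_target Demand-satisfied target as a proportion (default 0.75,
#'   i.e. the DS75 benchmark).
#' @param goal_year Year by which the target should be reached (default 2030).
#' @param current_year Baseline year of the assessment (default 2019).
#' @param cap_year Latest year searched for target attainment (default 2100).
#' @return A list of class \code{"at_config"}.
#' @export
at_config <- function(ds_target = 0.75, goal_year = 2030,
                      current_year = 2019, cap_year = 2100) {
  if (!(current_year < goal_year && goal_year <= cap_year))
    stop("need current_year < goal_year <= cap_year", call. = FALSE)
  if (ds_target <= 0 || ds_target >= 1)
    stop("ds_target must lie in (0, 1)", call. = FALSE)
  structure(list(ds_target = ds_target, goal_year = goal_year,
                 current_year = current_year, cap_year = cap_year),
            class = "at_config")
}

check_covers <- function(traj, from, to) {
  if (min(traj$year) > from || max(traj$year) < to)
    stop(sprintf("trajectory covers %d-%d but %d-%d is required",
                 min(traj$year), max(traj$year), from, to), call. = FALSE)
}

traj_at <- function(traj, year, col) {
  i <- match(year, traj$year)
  if (is.na(i)) stop("year ", year, " is not on the trajectory grid",
                     call. = FALSE)
  traj[[col]][i]
}

#' Earliest year a trajectory reaches the demand-satisfied target
#'
#' Scans the annual grid for the smallest year at or after the baseline year
#' in which projected demand satisfied is at or above the target. If the
#' target is not reached by the cap year the cap year is returned with
#' \code{capped = TRUE}, and downstream measures use the cap-year state.
#'
#' @param traj An \code{\link{fp_trajectory}} covering
#'   \code{[current_year, cap_year]}.
#' @param config An \code{\link{at_config}}.
#' @return A list with \code{t_star} (integer year) and \code{capped} (flag).
#' @export
find_target_year <- function(traj, config = at_config()) {
  check_covers(traj, config$current_year, config$cap_year)
  sub <- traj[traj$year >= config$current_year & traj$year <= config$cap_year, ]
  hit <- which(sub$ds >= config$ds_target)
  if (length(hit) == 0)
    list(t_star = config$cap_year, capped = TRUE)
  else
    list(t_star = sub$year[hit[1]], capped = FALSE)
}

#' Relative acceleration required to meet the target on time
#'
#' The factor by which the contraceptive-use transition must speed up:
#' the ratio of the projected number of years to target attainment,
#' \code{t_star - current_year}, to the number of years available,
#' \code{goal_year - current_year}. Returned unrounded; reports round to one
#' decimal, half away from zero.
#'
#' @param t_star Year of projected target attainment (vectorised).
#' @param config An \code{\link{at_config}}.
#' @return The acceleration ratio; 1 when \code{t_star} equals the goal year,
#'   below 1 for countries already on track.
#' @examples
#' relative_acceleration(2054)       # 35/11
#' relative_acceleration(2100)       # capped: 81/11
#' @export
relative_acceleration <- function(t_star, config = at_config()) {
  if (any(t_star < config$current_year))
    stop("t_star precedes current_year", call. = FALSE)
  (t_star - config$current_year) / (config$goal_year - config$current_year)
}

#' Target mCPR implied by the accelerated transition
#'
#' Under the AT method the mCPR projected for the attainment year becomes the
#' goal-year mCPR target: reaching the demand-satisfied benchmark earlier
#' requires the whole transition -- prevalence and demand together -- to reach
#' the \code{t_star} state by the goal year.
#'
#' @param traj An \code{\link{fp_trajectory}} whose grid contains
#'   \code{t_star}.
#' @param t_star Target attainment year (possibly the cap year).
#' @return Modern contraceptive prevalence at \code{t_star}, a proportion.
#' @export
target_mcpr <- function(traj, t_star) traj_at(traj, t_star, "modern")

#' mCPR target gap
#'
#' Difference between the target mCPR and the baseline-year mCPR. Negative
#' values arise for countries already on track; reports surface those as zero
#' with the on-track flag set.
#'
#' @param target,current Proportions in [0, 1].
#' @return \code{target - current}.
#' @export
mcpr_gap <- function(target, current) {
  if (any(c(target, current) < 0) || any(c(target, current) > 1))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  target - current
}

#' Additional modern-method users implied by an mCPR gap
#'
#' @param gap mCPR gap as a proportion (percentage points / 100).
#' @param mwra Number of married or in-union women of reproductive age.
#' @return \code{gap * mwra}, a person count.
#' @export
users_gap <- function(gap, mwra) {
  if (any(gap < 0) || any(mwra < 0))
    stop("gap and mwra must be non-negative", call. = FALSE)
  gap * mwra
}

#' Accelerated-transition trajectory
#'
#' Rescales time on the business-as-usual trajectory so that the state
#' projected for \code{t_star} is reached in the goal year: for
#' \code{t} between the baseline and goal years the accelerated state is the
#' BAU state at \code{current_year + rel_accel * (t - current_year)}, linearly
#' interpolated between grid years. Every accelerated state is therefore a BAU
#' state at some time, so the mCPR-demand relationship is preserved pointwise
#' and accelerated demand satisfied reaches the target exactly in the goal
#' year. Beyond the goal year the path continues as BAU time-shifted by
#' \code{t_star - goal_year}.
#'
#' @param bau The business-as-usual \code{\link{fp_trajectory}}.
#' @param t_star Attainment year; must exceed the goal year (otherwise no
#'   acceleration is needed and the BAU path applies directly).
#' @param config An \code{\link{at_config}}.
#' @return An \code{\link{fp_trajectory}} on the integer grid from the
#'   baseline year to the last year representable after the time shift.
#' @export
accelerated_trajectory <- function(bau, t_star, config = at_config()) {
  if (t_star <= config$goal_year)
    stop("t_star must exceed goal_year; the BAU path already meets the ",
         "target in time", call. = FALSE)
  check_covers(bau, config$current_year, t_star)
  accel <- relative_acceleration(t_star, config)
  years <- seq(config$current_year, max(bau$year) - (t_star - config$goal_year))
  src <- ifelse(years <= config$goal_year,
                config$current_year + accel * (years - config$current_year),
                years + (t_star - config$goal_year))
  interp <- function(col) stats::approx(bau$year, bau[[col]], xout = src)$y
  fp_trajectory(attr(bau, "country"), years,
                interp("modern"), interp("traditional"), interp("unmet"))
}

#' Assess one country with the accelerated-transition method
#'
#' End-to-end assessment: accepts either a business-as-usual trajectory or a
#' survey-observation data frame (which is fitted with
#' \code{\link{fit_fp_transition}} and projected), finds the target attainment
#' year, and computes the relative acceleration, target mCPR, mCPR gap and --
#' when a population denominator is supplied -- the additional-users gap.
#' Countries already meeting the target by the goal year are flagged on track
#' and their gaps reported as zero.
#'
#' @param x An \code{\link{fp_trajectory}} covering
#'   \code{[current_year, cap_year]}, a fitted \code{fp_transition}, or a
#'   survey-observation data frame.
#' @param mwra Optional count of married or in-union women of reproductive
#'   age, used to convert the mCPR gap to additional users.
#' @param config An \code{\link{at_config}}.
#' @return A list of class \code{"at_result"} with fields \code{country},
#'   \code{t_star}, \code{capped}, \code{rel_accel}, \code{target_mcpr},
#'   \code{current_mcpr}, \code{mcpr_gap}, \code{users_gap} (NA without
#'   \code{mwra}), \code{on_track}, plus the trajectory and config used.
#' @export
at_assess <- function(x, mwra = NULL, config = at_config()) {
  traj <- as_bau_trajectory(x, config)
  ty <- find_target_year(traj, config)
  accel <- relative_acceleration(ty$t_star, config)
  tmod <- target_mcpr(traj, ty$t_star)
  cur <- traj_at(traj, config$current_year, "modern")
  gap <- mcpr_gap(tmod, cur)
  on_track <- ty$t_star <= config$goal_year
  gap_rep <- if (on_track) 0 else gap
  structure(list(country = attr(traj, "country"), t_star = ty$t_star,
                 capped = ty$capped, rel_accel = accel, target_mcpr = tmod,
                 current_mcpr = cur, mcpr_gap = gap_rep,
                 users_gap = if (is.null(mwra)) NA_real_
                             else users_gap(gap_rep, mwra),
                 on_track = on_track, trajectory = traj, config = config),
            class = "at_result")
}

as_bau_trajectory <- function(x, config) {
  if (inherits(x, "fp_trajectory")) x
  else if (inherits(x, "fp_transition"))
    project(x, config$current_year, config$cap_year)
  else if (is.data.frame(x))
    project(fit_fp_transition(x), config$current_year, config$cap_year,
            country = if (!is.null(x$country)) as.character(x$country[1])
                      else "country")
  else stop("cannot interpret 'x' as a trajectory, fit or observation table",
            call. = FALSE)
}

#' @export
print.at_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("AT assessment: %s (DS target %.0f%% by %d)\n", x$country,
              100 * cfg$ds_target, cfg$goal_year))
  if (x$on_track) {
    cat(sprintf("  On track: target reached by %d under BAU.\n", x$t_star))
  } else {
    cat(sprintf("  Target year t* = %d%s\n", x$t_star,
                if (x$capped) " (capped: target not reached)" else ""))
    cat(sprintf("  Required acceleration: %.1f x\n",
                round_half_up(x$rel_accel)))
    cat(sprintf("  Target mCPR %.1f%%, gap %.1f percentage points\n",
                prop_to_pct(x$target_mcpr), prop_to_pct(x$mcpr_gap)))
    if (!is.na(x$users_gap))
      cat(sprintf("  Additional users needed: %.2f million\n",
                  x$users_gap / 1e6))
  }
  invisible(x)
}
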