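#' Demand-based (DB) target mCPR
#'
#' The demand-based comparator sets the goal-year mCPR target to the
#' demand-satisfied benchmark applied to the \emph{business-as-usual} total
#' demand projected for the goal year, i.e. it accelerates modern use only,
#' holding demand at its BAU level. The gap uses the same baseline-year mCPR
#' as the AT method, so AT-DB differences isolate the target definition.
#'
#' @param traj A business-as-usual \code{\link{fp_trajectory}} covering the
#'   goal year.
#' @param config An \code{\link{at_config}}.
#' @return A list of class \code{"db_result"} with \code{country},
#'   \code{db_target_mcpr} and \code{db_gap} (both proportions).
#' @export
db_target <- function(traj, config = at_config()) {
  demand_goal <- traj_at(traj, config$goal_year, "demand")
  tgt <- config$ds_target * demand_goal
  cur <- traj_at(traj, config$current_year, "modern")
  structure(list(country = attr(traj, "country"), db_target_mcpr = tgt,
                 db_gap = tgt - cur, config = config),
            class = "db_result")
}

#' @export
print.db_result <- function(x, ...) {
  cat(sprintf("DB target for %s: mCPR %.1f%% (gap %.1f pp)\n", x$country,
              prop_to_pct(x$db_target_mcpr), 100 * x$db_gap))
  invisible(x)
}

#' Compare AT and DB targets for the same country
#'
#' @param at An \code{at_result}.
#' @param db A \code{db_result} for the same country and configuration.
#' @return A one-row data frame with both targets and gaps (proportions) and
#'   their differences (\code{at_minus_db_target}, \code{at_minus_db_gap}).
#' @export
compare_at_db <- function(at, db) {
  if (!identical(at$country, db$country))
    stop("AT and DB results refer to different countries (", at$country,
         " vs ", db$country, ")", call. = FALSE)
  data.frame(country = at$country,
             at_target_mcpr = at$target_mcpr, db_target_mcpr = db$db_target_mcpr,
             at_gap = at$mcpr_gap, db_gap = db$db_gap,
             at_minus_db_target = at$target_mcpr - db$db_target_mcpr,
             at_minus_db_gap = at$mcpr_gap - db$db_gap,
             rel_accel = at$rel_accel)
}
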