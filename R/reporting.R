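# Checksum of the packaged assessment table (integrity check in load_table1).
.TABLE1_MD5 <- "331bceeec0d3dfb9a7f8e73690c2f61a"

#' Read and write survey observation tables
#'
#' The on-disk dialect is a header CSV with columns \code{country},
#' \code{year}, \code{modern_pct}, \code{traditional_pct}, \code{unmet_pct}
#' and optionally \code{obs_sd_pct}, all prevalence fields on the percent
#' scale. Reading converts to the internal proportion scale and validates
#' every row; writing is the exact inverse.
#'
#' @param path File path.
#' @return \code{read_survey_csv}: a data frame with proportion-scale columns
#'   \code{country}, \code{year}, \code{modern}, \code{traditional},
#'   \code{unmet}, \code{obs_sd}.
#' @export
read_survey_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = TRUE, fileEncoding = "UTF-8")
  need <- c("country", "year", "modern_pct", "traditional_pct", "unmet_pct")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("survey file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  obs <- data.frame(country = as.character(raw$country),
                    year = as.numeric(raw$year),
                    modern = pct_to_prop(raw$modern_pct),
                    traditional = pct_to_prop(raw$traditional_pct),
                    unmet = pct_to_prop(raw$unmet_pct),
                    obs_sd = if ("obs_sd_pct" %in% names(raw))
                      raw$obs_sd_pct / 100 else NA_real_)
  validate_state(obs)
  obs
}

#' @param observations Proportion-scale observation data frame (as returned
#'   by \code{read_survey_csv} or \code{\link{generate_observations}}).
#' @rdname read_survey_csv
#' @export
write_survey_csv <- function(observations, path) {
  out <- data.frame(country = observations$country,
                    year = observations$year,
                    modern_pct = prop_to_pct(observations$modern),
                    traditional_pct = prop_to_pct(observations$traditional),
                    unmet_pct = prop_to_pct(observations$unmet),
                    obs_sd_pct = if (!is.null(observations$obs_sd))
                      observations$obs_sd * 100 else NA_real_)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a projected trajectory as CSV
#'
#' Columns: \code{country}, \code{year}, \code{modern_pct},
#' \code{traditional_pct}, \code{unmet_pct}, \code{demand_pct},
#' \code{ds_pct}; percent scale.
#'
#' @param traj An \code{\link{fp_trajectory}}.
#' @param path File path.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- data.frame(country = attr(traj, "country"), year = traj$year,
                    modern_pct = prop_to_pct(traj$modern),
                    traditional_pct = prop_to_pct(traj$traditional),
                    unmet_pct = prop_to_pct(traj$unmet),
                    demand_pct = prop_to_pct(traj$demand),
                    ds_pct = prop_to_pct(traj$ds))
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Load the packaged DS75 assessment table
#'
#' Returns the packaged 50-country DS75 assessment table: for every country
#' projected to reach 75\% demand satisfied only after 2030, its target year,
#' target mCPR (percent), mCPR target gap (percentage points), users target
#' gap (millions), required acceleration (one decimal) and the demand-based
#' comparator column (stored verbatim and never interpreted by computation,
#' since its published semantics are ambiguous). Countries are ordered by
#' target year. Country names are UTF-8; an ASCII-normalised alias column is
#' provided for matching.
#'
#' @return A data frame with 50 rows and columns \code{country},
#'   \code{country_ascii}, \code{target_year}, \code{target_mcpr},
#'   \code{mcpr_gap}, \code{users_gap}, \code{acceleration},
#'   \code{db_column}.
#' @export
load_table1 <- function() {
  path <- system.file("extdata", "ds75_assessment_table.csv",
                      package = "fpaccel", mustWork = TRUE)
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .TABLE1_MD5))
    stop("packaged assessment table is corrupt (md5 ", md5, ")",
         call. = FALSE)
  tab <- utils::read.csv(path, check.names = TRUE, fileEncoding = "UTF-8")
  if (nrow(tab) != 50)
    stop("packaged assessment table must have 50 rows, found ", nrow(tab),
         call. = FALSE)
  tab
}

#' Summarise an assessment table or panel of AT results
#'
#' Computes the headline statistics of a DS75-style assessment: the number of
#' countries needing acceleration, the number whose (unrounded, recomputed)
#' relative acceleration is at least a threshold, and the ranges of the mCPR
#' gap and of the acceleration.
#'
#' @param rows Either a data frame with columns \code{target_year} and
#'   \code{mcpr_gap} (e.g. from \code{\link{load_table1}}) or a list of
#'   \code{at_result} objects.
#' @param accel_threshold Acceleration threshold for the count (default 3).
#' @param config An \code{\link{at_config}} used to recompute accelerations
#'   from target years.
#' @return A list with \code{n}, \code{n_accel_at_least}, \code{gap_min},
#'   \code{gap_max}, \code{accel_min}, \code{accel_max} (accelerations
#'   unrounded; gaps on the scale of the input).
#' @export
summarize_results <- function(rows, accel_threshold = 3,
                              config = at_config()) {
  if (is.list(rows) && !is.data.frame(rows) &&
      all(vapply(rows, inherits, logical(1), "at_result"))) {
    rows <- data.frame(
      target_year = vapply(rows, `[[`, numeric(1), "t_star"),
      mcpr_gap = vapply(rows, function(r) prop_to_pct(r$mcpr_gap),
                        numeric(1)))
  }
  if (!is.data.frame(rows) || nrow(rows) == 0)
    stop("need a non-empty assessment table", call. = FALSE)
  accel <- relative_acceleration(rows$target_year, config)
  list(n = nrow(rows),
       n_accel_at_least = sum(accel >= accel_threshold),
       gap_min = min(rows$mcpr_gap), gap_max = max(rows$mcpr_gap),
       accel_min = min(accel), accel_max = max(accel))
}

#' Write an assessment results table
#'
#' Serialises paired AT and DB assessments into the report CSV dialect
#' mirroring a published DS75 assessment table: columns \code{country},
#' \code{target_year}, \code{target_mcpr_pct}, \code{mcpr_gap_pp},
#' \code{users_gap_millions}, \code{acceleration} (one decimal, half away
#' from zero), \code{db_target_mcpr_pct}, \code{db_gap_pp},
#' \code{at_minus_db_pp}, \code{capped}, \code{on_track}. Numeric values
#' other than the acceleration are written in full precision so the file
#' round-trips.
#'
#' @param at_results List of \code{at_result} objects.
#' @param db_results Optional list of matching \code{db_result} objects.
#' @param path File path; with \code{NULL} the data frame is returned only.
#' @return The results data frame, invisibly when written to \code{path}.
#' @export
write_results <- function(at_results, db_results = NULL, path = NULL) {
  tab <- results_table(at_results, db_results)
  if (!is.null(path)) {
    utils::write.csv(tab, path, row.names = FALSE, fileEncoding = "UTF-8")
    return(invisible(tab))
  }
  tab
}

results_table <- function(at_results, db_results = NULL) {
  if (length(at_results) == 0) {
    return(data.frame(country = character(), target_year = numeric(),
                      target_mcpr_pct = numeric(), mcpr_gap_pp = numeric(),
                      users_gap_millions = numeric(), acceleration = numeric(),
                      db_target_mcpr_pct = numeric(), db_gap_pp = numeric(),
                      at_minus_db_pp = numeric(), capped = logical(),
                      on_track = logical()))
  }
  f <- function(fld, fn = identity)
    vapply(at_results, function(r) fn(r[[fld]]), vector(mode = "numeric", 1))
  tab <- data.frame(
    country = vapply(at_results, `[[`, character(1), "country"),
    target_year = f("t_star"),
    target_mcpr_pct = f("target_mcpr", prop_to_pct),
    mcpr_gap_pp = f("mcpr_gap", prop_to_pct),
    users_gap_millions = vapply(at_results, function(r)
      if (is.na(r$users_gap)) NA_real_ else r$users_gap / 1e6, numeric(1)),
    acceleration = round_half_up(f("rel_accel"), 1),
    capped = vapply(at_results, `[[`, logical(1), "capped"),
    on_track = vapply(at_results, `[[`, logical(1), "on_track"))
  if (!is.null(db_results)) {
    stopifnot(length(db_results) == length(at_results))
    tab$db_target_mcpr_pct <- vapply(db_results, function(r)
      prop_to_pct(r$db_target_mcpr), numeric(1))
    tab$db_gap_pp <- vapply(db_results, function(r) 100 * r$db_gap,
                            numeric(1))
    tab$at_minus_db_pp <- tab$target_mcpr_pct - tab$db_target_mcpr_pct
  }
  tab
}
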