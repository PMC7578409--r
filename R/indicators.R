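#' @keywords internal
"_PACKAGE"

# Tolerance absorbing floating-point accumulation in sum-to-one checks.
.SUM_TOL <- 1e-9

#' Prevalence state of married or in-union women at one point in time
#'
#' Bundles the three components of contraceptive demand among married or
#' in-union women aged 15-49: the proportion using a modern method, the
#' proportion using a traditional method, and the proportion with unmet need
#' for family planning. All values are proportions in \code{[0, 1]}; their sum
#' cannot exceed 1 because the three groups are disjoint.
#'
#' @param modern Proportion using modern contraceptive methods.
#' @param traditional Proportion using traditional methods.
#' @param unmet Proportion with unmet need for family planning.
#' @return A named list of class \code{"prevalence_state"}. Vectorised: all
#'   three arguments may be equal-length vectors.
#' @examples
#' st <- prevalence_state(0.546, 0.05, 0.132)
#' total_demand(st)
#' demand_satisfied(st)
#' @export
prevalence_state <- function(modern, traditional, unmet) {
  st <- structure(list(modern = as.numeric(modern),
                       traditional = as.numeric(traditional),
                       unmet = as.numeric(unmet)),
                  class = "prevalence_state")
  validate_state(st)
  st
}

#' Validate a prevalence state
#'
#' Checks that each component is a non-negative proportion and that the
#' components sum to at most 1 (within a tolerance of 1e-9). The error message
#' names the offending component.
#'
#' @param state A \code{prevalence_state} or a list with fields
#'   \code{modern}, \code{traditional}, \code{unmet}.
#' @return The state, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_state <- function(state) {
  for (comp in c("modern", "traditional", "unmet")) {
    x <- state[[comp]]
    if (is.null(x) || !is.numeric(x) || anyNA(x))
      stop("component '", comp, "' is missing or non-numeric", call. = FALSE)
    if (any(x < 0))
      stop("component '", comp, "' is negative", call. = FALSE)
    if (any(x > 1 + .SUM_TOL))
      stop("component '", comp, "' exceeds 1", call. = FALSE)
  }
  tot <- state$modern + state$traditional + state$unmet
  if (any(tot > 1 + .SUM_TOL))
    stop("components modern + traditional + unmet exceed 1 (",
         format(max(tot)), ")", call. = FALSE)
  invisible(state)
}

#' Total demand for family planning
#'
#' Total demand is contraceptive prevalence (modern plus traditional use) plus
#' unmet need.
#'
#' @param state A \code{prevalence_state}.
#' @return Total demand as a proportion (vectorised).
#' @export
total_demand <- function(state) {
  validate_state(state)
  state$modern + state$traditional + state$unmet
}

#' Demand for family planning satisfied with modern methods
#'
#' The ratio of modern contraceptive prevalence to total demand (SDG indicator
#' 3.7.1). When total demand is zero the ratio is defined as 0 by convention;
#' that case never arises on projected trajectories with positive prevalence.
#'
#' @param state A \code{prevalence_state}.
#' @return Demand satisfied as a proportion in \code{[0, 1]} (vectorised).
#' @export
demand_satisfied <- function(state) {
  d <- total_demand(state)
  ds <- ifelse(d > 0, state$modern / d, 0)
  unname(ds)
}

#' Convert between percent and proportion scales
#'
#' Tables and files use the percent scale; all internal computation uses
#' proportions in \code{[0, 1]}. These helpers convert exactly (division or
#' multiplication by 100) and validate the input range.
#'
#' @param x Numeric vector: percentages in \code{[0, 100]} for
#'   \code{pct_to_prop}, proportions in \code{[0, 1]} for \code{prop_to_pct}.
#' @return The converted numeric vector.
#' @examples
#' pct_to_prop(54.6)
#' prop_to_pct(0.75)
#' @export
pct_to_prop <- function(x) {
  if (any(x < 0 | x > 100, na.rm = TRUE))
    stop("percent values must lie in [0, 100]", call. = FALSE)
  x / 100
}

#' @rdname pct_to_prop
#' @export
prop_to_pct <- function(x) {
  if (any(x < 0 | x > 1 + .SUM_TOL, na.rm = TRUE))
    stop("proportions must lie in [0, 1]", call. = FALSE)
  x * 100
}

# Round half away from zero (report convention; base round() is half-to-even).
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.prevalence_state <- function(x, ...) {
  cat("Prevalence state (proportions of MWRA):\n")
  print(data.frame(modern = x$modern, traditional = x$traditional,
                   unmet = x$unmet,
                   demand = x$modern + x$traditional + x$unmet,
                   ds = demand_satisfied(x)), ...)
  invisible(x)
}
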