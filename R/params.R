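#' Per-visit service times
#'
#' Clinical time assumed for each of the three visit types recorded in the
#' oral health survey: check-up/exam/cleaning, routine treatment and
#' emergency treatment.
#'
#' @param minutes_checkup,minutes_routine,minutes_emergency Minutes per visit,
#'   all strictly positive. Defaults are the baseline assumption of
#'   20/30/40 minutes.
#' @return An object of class `service_times`.
#' @examples
#' service_times()
#' service_times(minutes_emergency = 60)
#' @export
service_times <- function(minutes_checkup = 20, minutes_routine = 30,
                          minutes_emergency = 40) {
  x <- structure(
    list(minutes_checkup = minutes_checkup,
         minutes_routine = minutes_routine,
         minutes_emergency = minutes_emergency),
    class = "service_times")
  validate_service_times(x)
}

validate_service_times <- function(x) {
  for (f in names(x)) check_scalar(x[[f]], f, lower = 0, lower_open = TRUE)
  x
}

#' Annual practitioner capacity parameters
#'
#' Determine the clinical minutes one full-time practitioner delivers to the
#' adult (15+) population per calendar year. `adult_care_share` scales weekly
#' hours to exclude time spent with patients outside the modelled population
#' (e.g. children seen privately); setting it to 0.8 reproduces a reduction of
#' weekly hours to 80% of baseline.
#'
#' @param weeks_per_year Working weeks per year, in (0, 52].
#' @param hours_per_week Hours worked per week, in (0, 168].
#' @param clinical_time_fraction Fraction of working time spent with patients,
#'   in (0, 1].
#' @param adult_care_share Fraction of clinical time devoted to the modelled
#'   adult population, in (0, 1].
#' @return An object of class `capacity_params`.
#' @seealso [annual_capacity_minutes()]
#' @export
capacity_params <- function(weeks_per_year = 45, hours_per_week = 39,
                            clinical_time_fraction = 0.9,
                            adult_care_share = 1) {
  x <- structure(
    list(weeks_per_year = weeks_per_year,
         hours_per_week = hours_per_week,
         clinical_time_fraction = clinical_time_fraction,
         adult_care_share = adult_care_share),
    class = "capacity_params")
  validate_capacity_params(x)
}

validate_capacity_params <- function(x) {
  check_scalar(x$weeks_per_year, "weeks_per_year", 0, 52, lower_open = TRUE)
  check_scalar(x$hours_per_week, "hours_per_week", 0, 168, lower_open = TRUE)
  check_fraction(x$clinical_time_fraction, "clinical_time_fraction",
                 lower_open = TRUE)
  check_fraction(x$adult_care_share, "adult_care_share", lower_open = TRUE)
  x
}

#' Workforce participation and part-time profile
#'
#' Parameters converting registered headcount into FTE supply: the
#' participation rate (fraction of registrants actively delivering clinical
#' care) and the part-time working profile from which the activity rate is
#' derived.
#'
#' @param participation_rate Fraction of registrants in active practice.
#' @param part_time_share Fraction of active practitioners working part-time.
#' @param part_time_hours_fraction Fraction of full-time hours worked by a
#'   part-time practitioner.
#' @return An object of class `supply_params`.
#' @seealso [activity_rate()], [fte_supply()]
#' @export
supply_params <- function(participation_rate = 0.95, part_time_share = 0.30,
                          part_time_hours_fraction = 0.50) {
  x <- structure(
    list(participation_rate = participation_rate,
         part_time_share = part_time_share,
         part_time_hours_fraction = part_time_hours_fraction),
    class = "supply_params")
  validate_supply_params(x)
}

validate_supply_params <- function(x) {
  for (f in names(x)) check_fraction(x[[f]], f)
  x
}

#' Graduate training pipeline
#'
#' Describes the undergraduate dental training pipeline: annual intake places
#' are adjusted for non-progression to year 2 and attrition thereafter, and
#' graduates are further adjusted for the share entering domestic employment.
#' Graduates from the cohort entering in year `y` join the workforce stock at
#' the end of year `y + course_length`.
#'
#' @param intake_places Undergraduate places offered per year (>= 0).
#' @param nonprogression_y2 Fraction not progressing to year 2, in \[0, 1\].
#' @param attrition_rate Fraction lost after year 2, in \[0, 1\].
#' @param domestic_employment_share Fraction of graduates entering domestic
#'   employment, in \[0, 1\].
#' @param course_length Course length in whole years (>= 1), default 5.
#' @return An object of class `graduate_pipeline`.
#' @seealso [new_graduates()]
#' @export
graduate_pipeline <- function(intake_places, nonprogression_y2 = 0,
                              attrition_rate = 0,
                              domestic_employment_share = 1,
                              course_length = 5) {
  x <- structure(
    list(intake_places = intake_places,
         nonprogression_y2 = nonprogression_y2,
         attrition_rate = attrition_rate,
         domestic_employment_share = domestic_employment_share,
         course_length = course_length),
    class = "graduate_pipeline")
  validate_graduate_pipeline(x)
}

validate_graduate_pipeline <- function(x) {
  check_scalar(x$intake_places, "intake_places", lower = 0)
  check_fraction(x$nonprogression_y2, "nonprogression_y2")
  check_fraction(x$attrition_rate, "attrition_rate")
  check_fraction(x$domestic_employment_share, "domestic_employment_share")
  check_scalar(x$course_length, "course_length", lower = 1, integerish = TRUE)
  x
}

#' Annual workforce flow assumptions
#'
#' One row per calendar year with inflow and outflow headcounts. Inflows
#' cover foreign-trained registrants, domestically trained registrants
#' returning from abroad and practitioners returning from a period of absence;
#' new graduates are handled separately through the [graduate_pipeline()].
#' Outflows cover emigration, absence (career breaks) and retirement/death.
#' Years missing from the table are resolved by carrying the last specified
#' year's values forward.
#'
#' @param year Calendar year(s); must be unique.
#' @param inflow_foreign_trained,inflow_returning_domestic,inflow_return_from_absence
#'   Inflow headcounts per year (>= 0).
#' @param outflow_emigration,outflow_absence,outflow_retirement_death Outflow
#'   headcounts per year (>= 0).
#' @return A tibble of class `flow_assumptions`.
#' @export
flow_assumptions <- function(year,
                             inflow_foreign_trained = 0,
                             inflow_returning_domestic = 0,
                             inflow_return_from_absence = 0,
                             outflow_emigration = 0,
                             outflow_absence = 0,
                             outflow_retirement_death = 0) {
  x <- tibble::tibble(
    year = as.integer(year),
    inflow_foreign_trained = inflow_foreign_trained,
    inflow_returning_domestic = inflow_returning_domestic,
    inflow_return_from_absence = inflow_return_from_absence,
    outflow_emigration = outflow_emigration,
    outflow_absence = outflow_absence,
    outflow_retirement_death = outflow_retirement_death)
  x <- dplyr::arrange(x, .data$year)
  class(x) <- c("flow_assumptions", class(x))
  validate_flow_assumptions(x)
}

flow_components <- function() {
  c("inflow_foreign_trained", "inflow_returning_domestic",
    "inflow_return_from_absence", "outflow_emigration", "outflow_absence",
    "outflow_retirement_death")
}

validate_flow_assumptions <- function(x) {
  if (anyDuplicated(x$year)) {
    abort_config("flow assumptions contain duplicated years")
  }
  for (f in flow_components()) {
    if (any(!is.finite(x[[f]])) || any(x[[f]] < 0)) {
      abort_config("flow component '%s' must be finite and >= 0", f)
    }
  }
  x
}

#' Frequency-category to visit-count mapping
#'
#' Converts the survey's ordinal visit-frequency categories into annual visit
#' counts. The survey instrument records a categorical frequency, so the count
#' assigned to each category is a modelling choice; the default maps
#' once to 1, twice to 2 and three-or-more to 3.5 visits per year. The mapping
#' must be non-negative and non-decreasing in category order, and is echoed
#' into output metadata because estimates are sensitive to it.
#'
#' @param ... Named non-negative numbers, one per frequency category, in
#'   category order.
#' @return A named numeric vector of class `frequency_mapping`.
#' @examples
#' frequency_mapping()
#' frequency_mapping(once = 1, twice = 2, three_or_more = 4)
#' @export
frequency_mapping <- function(...) {
  vals <- c(...)
  if (length(vals) == 0) {
    vals <- c(once = 1, twice = 2, three_or_more = 3.5)
  }
  if (is.null(names(vals)) || any(names(vals) == "")) {
    abort_config("every frequency category must be named")
  }
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort_config("visit counts must be finite and >= 0")
  }
  if (is.unsorted(vals)) {
    abort_config("frequency mapping must be non-decreasing in category order")
  }
  structure(vals, class = "frequency_mapping")
}

#' Full baseline parameter set for a projection run
#'
#' Bundles every tunable parameter of the supply and requirement sides into a
#' single object that [run_projection()] consumes and scenario overrides act
#' on. Defaults are the baseline assumptions: service times 20/30/40 minutes,
#' 45 working weeks of 39 hours with 90% clinical time, participation 95%,
#' 30% part-time at 50% hours, horizon 2017--2050.
#'
#' @param initial_stock Registered headcount at the end of the year before the
#'   horizon starts.
#' @param flows A [flow_assumptions()] table (default: all flows zero).
#' @param pipeline A [graduate_pipeline()] or `NULL` for no graduate inflow.
#' @param supply A [supply_params()] object.
#' @param times A [service_times()] object.
#' @param capacity A [capacity_params()] object.
#' @param mapping A [frequency_mapping()].
#' @param horizon Contiguous integer vector of projection years.
#' @return An object of class `wp_params`.
#' @export
baseline_params <- function(initial_stock,
                            flows = flow_assumptions(year = horizon[1]),
                            pipeline = NULL,
                            supply = supply_params(),
                            times = service_times(),
                            capacity = capacity_params(),
                            mapping = frequency_mapping(),
                            horizon = 2017:2050) {
  horizon <- as.integer(horizon)
  if (length(horizon) == 0 || any(diff(horizon) != 1L)) {
    abort_config("'horizon' must be a non-empty contiguous range of years")
  }
  check_scalar(initial_stock, "initial_stock", lower = 0)
  stopifnot(inherits(flows, "flow_assumptions"),
            inherits(supply, "supply_params"),
            inherits(times, "service_times"),
            inherits(capacity, "capacity_params"),
            inherits(mapping, "frequency_mapping"))
  if (!is.null(pipeline)) stopifnot(inherits(pipeline, "graduate_pipeline"))
  structure(
    list(initial_stock = initial_stock, flows = flows, pipeline = pipeline,
         supply = supply, times = times, capacity = capacity,
         mapping = mapping, horizon = horizon),
    class = "wp_params")
}

#' @export
print.wp_params <- function(x, ...) {
  cat("<workforce planning parameters>\n")
  cat(sprintf("  horizon        : %d-%d\n", min(x$horizon), max(x$horizon)))
  cat(sprintf("  initial stock  : %g registrants\n", x$initial_stock))
  cat(sprintf("  service times  : %g/%g/%g min (checkup/routine/emergency)\n",
              x$times$minutes_checkup, x$times$minutes_routine,
              x$times$minutes_emergency))
  cat(sprintf("  capacity       : %g wk x %g h, clinical %g, adult share %g\n",
              x$capacity$weeks_per_year, x$capacity$hours_per_week,
              x$capacity$clinical_time_fraction, x$capacity$adult_care_share))
  cat(sprintf("  supply         : participation %g, part-time %g @ %g\n",
              x$supply$participation_rate, x$supply$part_time_share,
              x$supply$part_time_hours_fraction))
  cat(sprintf("  pipeline       : %s\n",
              if (is.null(x$pipeline)) "none"
              else sprintf("%g places, %g-year course", x$pipeline$intake_places,
                           x$pipeline$course_length)))
  invisible(x)
}
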