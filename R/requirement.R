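#' Population table by year, sex and age band
#'
#' Validates a long-format population table: one row per year x sex x age
#' band with a non-negative `persons` count, covering all eight sex x
#' age-band strata in every year present.
#'
#' @param x Data frame with columns `year`, `sex`, `age_band`, `persons`.
#' @return A tibble of class `population_table`.
#' @seealso [population_at()], [gen_population()], [read_population_csv()]
#' @export
population_table <- function(x) {
  x <- tibble::as_tibble(x)
  needed <- c("year", "sex", "age_band", "persons")
  missing <- setdiff(needed, names(x))
  if (length(missing)) {
    abort_config("population table lacks column(s): %s",
                 paste(missing, collapse = ", "))
  }
  bad_sex <- setdiff(unique(x$sex), SEX_LEVELS)
  if (length(bad_sex)) {
    abort_config("unknown sex value(s) in population table: %s",
                 paste(bad_sex, collapse = ", "))
  }
  bad_band <- setdiff(unique(x$age_band), AGE_BAND_LEVELS)
  if (length(bad_band)) {
    abort_config("unknown age_band value(s) in population table: %s",
                 paste(bad_band, collapse = ", "))
  }
  if (any(!is.finite(x$persons)) || any(x$persons < 0)) {
    abort_config("'persons' must be finite and >= 0")
  }
  x$year <- as.integer(x$year)
  cells <- table(x$year)
  if (any(cells != length(SEX_LEVELS) * length(AGE_BAND_LEVELS))) {
    abort_config("every year must cover all %d sex x age-band strata exactly once",
                 length(SEX_LEVELS) * length(AGE_BAND_LEVELS))
  }
  x$sex <- factor(x$sex, SEX_LEVELS)
  x$age_band <- factor(x$age_band, AGE_BAND_LEVELS)
  class(x) <- c("population_table", class(x))
  x
}

#' Population of each stratum in a given year
#'
#' Years absent from the table are linearly interpolated between the
#' surrounding provided years; requesting a year outside the table's range is
#' an error (no extrapolation).
#'
#' @param population A [population_table()].
#' @param year Calendar year.
#' @return Tibble with `sex`, `age_band`, `persons` for that year.
#' @export
population_at <- function(population, year) {
  stopifnot(inherits(population, "population_table"))
  check_scalar(year, "year", integerish = TRUE)
  yrs <- sort(unique(population$year))
  if (year %in% yrs) {
    out <- population[population$year == year, c("sex", "age_band", "persons")]
    return(tibble::as_tibble(out))
  }
  if (year < min(yrs) || year > max(yrs)) {
    abort_config("year %d outside the population table range %d-%d (no extrapolation)",
                 year, min(yrs), max(yrs))
  }
  y0 <- max(yrs[yrs < year])
  y1 <- min(yrs[yrs > year])
  p0 <- population[population$year == y0, c("sex", "age_band", "persons")]
  p1 <- population[population$year == y1, c("sex", "age_band", "persons")]
  out <- dplyr::inner_join(p0, p1, by = c("sex", "age_band"),
                           suffix = c("0", "1"))
  frac <- (year - y0) / (y1 - y0)
  out$persons <- out$persons0 + frac * (out$persons1 - out$persons0)
  tibble::as_tibble(out[, c("sex", "age_band", "persons")])
}

#' Total annual visits by stratum and visit type
#'
#' Applies the per-capita stratum visit rates to the population of a given
#' year: `visits = persons x per_capita_rate`, separately for each visit
#' type. Rates are held constant across years (constant-health-status
#' assumption); a populated stratum with an undefined rate is a configuration
#' error.
#'
#' @param rates A [estimate_need_rates()] result aggregated over health
#'   status (sex x age band only).
#' @param population A [population_table()].
#' @param year Calendar year (interpolated if absent, see [population_at()]).
#' @return Tibble with one row per stratum: `sex`, `age_band`, `persons`,
#'   `visits_checkup`, `visits_routine`, `visits_emergency`.
#' @export
total_visits <- function(rates, population, year) {
  stopifnot(inherits(rates, "need_rates"))
  if ("health_status" %in% names(rates)) {
    abort_config(paste0(
      "rates are stratified by health status; the requirement calculation ",
      "needs rates aggregated to sex x age band ",
      "(re-run estimate_need_rates with use_health_status = FALSE)"))
  }
  pop <- population_at(population, year)
  joined <- dplyr::inner_join(pop, rates, by = c("sex", "age_band"))
  undefined <- !joined$defined & joined$persons > 0
  if (any(undefined)) {
    abort_config("no visit rate defined for populated stratum/strata: %s",
                 paste(paste(joined$sex[undefined], joined$age_band[undefined]),
                       collapse = "; "))
  }
  tibble::tibble(
    sex = joined$sex, age_band = joined$age_band, persons = joined$persons,
    visits_checkup = joined$persons * dplyr::coalesce(joined$rate_checkup, 0),
    visits_routine = joined$persons * dplyr::coalesce(joined$rate_routine, 0),
    visits_emergency = joined$persons *
      dplyr::coalesce(joined$rate_emergency, 0))
}

#' Total service minutes for a set of visits
#'
#' Weights the visit counts by the assumed minutes per visit type and sums:
#' the population's annual requirement for clinical time.
#'
#' @param visits Either a [total_visits()] result or a numeric vector of
#'   three visit counts in the order check-up, routine, emergency.
#' @param times A [service_times()] object.
#' @return Total minutes (scalar).
#' @examples
#' service_minutes(c(1, 1, 1), service_times(20, 30, 40)) # 90
#' @export
service_minutes <- function(visits, times = service_times()) {
  validate_service_times(times)
  if (is.data.frame(visits)) {
    v <- c(sum(visits$visits_checkup), sum(visits$visits_routine),
           sum(visits$visits_emergency))
  } else {
    stopifnot(is.numeric(visits), length(visits) == 3)
    v <- visits
  }
  if (any(!is.finite(v)) || any(v < 0)) {
    abort_config("visit counts must be finite and >= 0")
  }
  sum(v * c(times$minutes_checkup, times$minutes_routine,
            times$minutes_emergency))
}

#' Annual clinical capacity of one full-time practitioner
#'
#' Minutes of clinical time for the modelled population that one FTE
#' practitioner delivers per year:
#' `weeks_per_year x hours_per_week x clinical_time_fraction x
#' adult_care_share x 60`. Full precision is retained; rounding to whole
#' hours happens only in the reporting layer (see [report_hours()]). The
#' baseline 45 weeks x 39 h x 90% clinical time gives 94 770 minutes,
#' reported as 1580 h.
#'
#' @param params A [capacity_params()] object.
#' @return Minutes per FTE per year.
#' @examples
#' annual_capacity_minutes(capacity_params(45, 39, 0.9, 1)) # 94770
#' @export
annual_capacity_minutes <- function(params = capacity_params()) {
  validate_capacity_params(params)
  params$weeks_per_year * params$hours_per_week *
    params$clinical_time_fraction * params$adult_care_share * 60
}

#' FTE provider requirement from total service minutes
#'
#' Converts the population's total annual service minutes into the equivalent
#' number of full-time practitioners by dividing by the annual clinical
#' capacity of one FTE.
#'
#' @param total_minutes Total service minutes (>= 0).
#' @param capacity Minutes per FTE per year (> 0), from
#'   [annual_capacity_minutes()].
#' @return FTE provider requirement.
#' @export
fte_requirement <- function(total_minutes, capacity) {
  if (any(!is.finite(total_minutes)) || any(total_minutes < 0)) {
    abort_config("'total_minutes' must be finite and >= 0")
  }
  check_scalar(capacity, "capacity", lower = 0, lower_open = TRUE)
  total_minutes / capacity
}

#' Reporting-layer rounding
#'
#' All internal arithmetic is carried at full precision; these helpers apply
#' the printed precision used in reports: FTEs and headcounts to the nearest
#' integer, annual hours to the nearest hour, supply/requirement ratios to
#' one decimal.
#'
#' @param minutes,fte,ratio Values to round for display.
#' @return Rounded value.
#' @examples
#' report_hours(annual_capacity_minutes(capacity_params())) # 1580
#' report_ratio(1985 / 899) # 2.2
#' @name reporting
NULL

#' @rdname reporting
#' @export
report_hours <- function(minutes) round(minutes / 60)

#' @rdname reporting
#' @export
report_fte <- function(fte) round(fte)

#' @rdname reporting
#' @export
report_ratio <- function(ratio) round(ratio, 1)
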