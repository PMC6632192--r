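#' Activity rate from the part-time working profile
#'
#' The activity rate is the average fraction of full-time hours worked across
#' the active workforce: full-timers contribute 1, part-timers contribute
#' `part_time_hours_fraction`, weighted by the part-time share. With 30% of
#' dentists working part-time at 50% of full-time hours the activity rate is
#' 85%.
#'
#' @param part_time_share Fraction of practitioners working part-time.
#' @param part_time_hours_fraction Fraction of full-time hours a part-time
#'   practitioner works.
#' @return The activity rate, a fraction in
#'   \[`part_time_hours_fraction`, 1\]. Vectorised over both arguments.
#' @examples
#' activity_rate(0.30, 0.50) # 0.85
#' @export
activity_rate <- function(part_time_share, part_time_hours_fraction) {
  if (any(!is.finite(part_time_share)) || any(part_time_share < 0) ||
      any(part_time_share > 1)) {
    abort_config("'part_time_share' must be within [0, 1]")
  }
  if (any(!is.finite(part_time_hours_fraction)) ||
      any(part_time_hours_fraction < 0) || any(part_time_hours_fraction > 1)) {
    abort_config("'part_time_hours_fraction' must be within [0, 1]")
  }
  (1 - part_time_share) + part_time_share * part_time_hours_fraction
}

#' Graduates available for domestic work from one intake cohort
#'
#' Intake places are adjusted for non-progression to year 2 of the course and
#' attrition thereafter, then for the share of graduates entering domestic
#' employment. The result is a (possibly fractional) headcount that joins the
#' workforce stock at the end of year `cohort_year + course_length`.
#'
#' @param pipeline A [graduate_pipeline()].
#' @param cohort_year Calendar year the cohort entered the course. Only used
#'   for timing (see [project_stock()]); the steady-state pipeline produces the
#'   same headcount for every cohort.
#' @return Graduate headcount available for work.
#' @examples
#' new_graduates(graduate_pipeline(100, 0.10, 0.05, 0.80)) # 68.4
#' @export
new_graduates <- function(pipeline, cohort_year = NA_integer_) {
  validate_graduate_pipeline(pipeline)
  pipeline$intake_places * (1 - pipeline$nonprogression_y2) *
    (1 - pipeline$attrition_rate) * pipeline$domestic_employment_share
}

#' Register snapshot
#'
#' A snapshot of the practitioner register at the end of a calendar year. Each
#' entry carries the registrant identifier, registration date, qualification
#' year, qualification origin (domestic or foreign) and practice status
#' (`general_practice`, or `excluded` for e.g. public dental service, oral
#' surgeons, orthodontists and known full-time academics).
#'
#' @param as_of_year Calendar year the snapshot refers to.
#' @param entries Data frame with columns `registrant_id`, `date_registered`
#'   (`Date` or ISO 8601 string), `year_qualified`, `qualification_origin` and
#'   `practice_status`.
#' @return An object of class `register_snapshot`.
#' @seealso [diff_registers()], [read_register_csv()]
#' @export
register_snapshot <- function(as_of_year, entries) {
  check_scalar(as_of_year, "as_of_year", integerish = TRUE)
  entries <- tibble::as_tibble(entries)
  needed <- c("registrant_id", "date_registered", "year_qualified",
              "qualification_origin", "practice_status")
  missing <- setdiff(needed, names(entries))
  if (length(missing)) {
    abort_config("register entries lack column(s): %s",
                 paste(missing, collapse = ", "))
  }
  entries$registrant_id <- as.character(entries$registrant_id)
  entries$date_registered <- as.Date(entries$date_registered)
  entries$year_qualified <- as.integer(entries$year_qualified)
  if (anyDuplicated(entries$registrant_id)) {
    abort_config("duplicate registrant_id within a register snapshot")
  }
  bad_origin <- setdiff(unique(entries$qualification_origin),
                        c("domestic", "foreign"))
  if (length(bad_origin)) {
    abort_config("unknown qualification_origin: %s",
                 paste(bad_origin, collapse = ", "))
  }
  bad_status <- setdiff(unique(entries$practice_status),
                        c("general_practice", "excluded"))
  if (length(bad_status)) {
    abort_config("unknown practice_status: %s",
                 paste(bad_status, collapse = ", "))
  }
  reg_year <- as.integer(format(entries$date_registered, "%Y"))
  if (any(entries$year_qualified > reg_year, na.rm = TRUE)) {
    abort_config("year_qualified later than year of registration for %d entr%s",
                 sum(entries$year_qualified > reg_year, na.rm = TRUE),
                 if (sum(entries$year_qualified > reg_year, na.rm = TRUE) == 1)
                   "y" else "ies")
  }
  structure(list(as_of_year = as.integer(as_of_year), entries = entries),
            class = "register_snapshot")
}

#' @export
print.register_snapshot <- function(x, ...) {
  cat(sprintf("<register snapshot %d: %d registrants (%d domestic, %d foreign)>\n",
              x$as_of_year, nrow(x$entries),
              sum(x$entries$qualification_origin == "domestic"),
              sum(x$entries$qualification_origin == "foreign")))
  invisible(x)
}

#' Estimate workforce flows by diffing two register snapshots
#'
#' Entries present only in the later snapshot are inflows, classified by
#' qualification origin and qualification year: domestic registrants qualified
#' after the earlier snapshot year are new-graduate inflow, other domestic
#' registrants are returning-domestic inflow, and foreign-qualified
#' registrants are foreign-trained inflow. Entries present only in the earlier
#' snapshot are outflows; without auxiliary labels their subtype (emigration,
#' absence, retirement) cannot be determined, so they are reported as a single
#' unclassified count, optionally with a qualification-age retirement
#' heuristic (qualified at least `retirement_years` before the later snapshot,
#' hence assumed at least 65 years old).
#'
#' @param earlier,later [register_snapshot()]s with
#'   `earlier$as_of_year < later$as_of_year`.
#' @param retirement_heuristic If `TRUE`, split the outflow into an estimated
#'   retirement/death component and an unclassified remainder.
#' @param retirement_years Years since qualification above which an outflow is
#'   attributed to retirement; default 41.
#' @return An object of class `register_flows`: a list with the two snapshot
#'   years, a named `counts` vector (`inflow_graduates`,
#'   `inflow_foreign_trained`, `inflow_returning_domestic`,
#'   `outflow_unclassified` and, with the heuristic,
#'   `outflow_retirement_est`), and the inflow/outflow entry tables.
#' @examples
#' pair <- gen_register_pair(synthetic_truth(), n0 = 100, seed = 1)
#' diff_registers(pair$earlier, pair$later)
#' @export
diff_registers <- function(earlier, later, retirement_heuristic = FALSE,
                           retirement_years = 41) {
  stopifnot(inherits(earlier, "register_snapshot"),
            inherits(later, "register_snapshot"))
  if (!(earlier$as_of_year < later$as_of_year)) {
    abort_config("'earlier' snapshot (%d) must predate 'later' (%d)",
                 earlier$as_of_year, later$as_of_year)
  }
  ids0 <- earlier$entries$registrant_id
  ids1 <- later$entries$registrant_id
  inflow <- later$entries[!(ids1 %in% ids0), , drop = FALSE]
  outflow <- earlier$entries[!(ids0 %in% ids1), , drop = FALSE]

  is_foreign <- inflow$qualification_origin == "foreign"
  is_new_grad <- !is_foreign & inflow$year_qualified > earlier$as_of_year
  counts <- c(
    inflow_graduates = sum(is_new_grad),
    inflow_foreign_trained = sum(is_foreign),
    inflow_returning_domestic = sum(!is_foreign & !is_new_grad))
  if (retirement_heuristic) {
    retired <- outflow$year_qualified <= later$as_of_year - retirement_years
    counts <- c(counts,
                outflow_retirement_est = sum(retired),
                outflow_unclassified = sum(!retired))
  } else {
    counts <- c(counts, outflow_unclassified = nrow(outflow))
  }
  # conservation: |later| = |earlier| + inflows - outflows
  stopifnot(nrow(later$entries) ==
              nrow(earlier$entries) + nrow(inflow) - nrow(outflow))
  structure(
    list(from_year = earlier$as_of_year, to_year = later$as_of_year,
         counts = counts, total_inflow = nrow(inflow),
         total_outflow = nrow(outflow),
         inflow_entries = inflow, outflow_entries = outflow),
    class = "register_flows")
}

#' @export
print.register_flows <- function(x, ...) {
  cat(sprintf("<register flows %d -> %d: %d in, %d out>\n",
              x$from_year, x$to_year, x$total_inflow, x$total_outflow))
  print(x$counts)
  invisible(x)
}

# carry-forward rule: a year missing from the flow table inherits the most
# recent specified year's values; years before the first specified year have
# no carry-forward source and are a configuration error
flows_for_year <- function(flows, year) {
  zero <- stats::setNames(rep(0, length(flow_components())), flow_components())
  if (is.null(flows)) return(zero)
  stopifnot(inherits(flows, "flow_assumptions"))
  avail <- flows$year[flows$year <= year]
  if (length(avail) == 0) {
    abort_config(
      "no flow assumptions for year %d and no earlier year to carry forward",
      year)
  }
  row <- flows[flows$year == max(avail), flow_components()]
  unlist(row)
}

#' Project the registered workforce stock over a planning horizon
#'
#' Annual stock-flow recursion: the stock at the end of year `t` equals the
#' stock at the end of year `t - 1`, plus the year's inflows and new
#' graduates, minus the year's outflows. Flow assumptions missing for a year
#' are carried forward from the last specified year. Graduates from the cohort
#' that entered the course in year `t - course_length` arrive at the end of
#' year `t`. If outflows would drive the stock negative it is floored at zero
#' with a warning.
#'
#' @param initial_stock Headcount at the end of the year before the horizon.
#' @param flows A [flow_assumptions()] table, or `NULL` for zero flows.
#' @param pipeline A [graduate_pipeline()], or `NULL` for no graduate inflow.
#' @param horizon Contiguous integer vector of projection years.
#' @return A tibble of class `stock_series` with columns `year`, `inflow`,
#'   `graduates`, `outflow` and `stock` (end-of-year headcount); the starting
#'   stock is kept in the `initial_stock` attribute.
#' @examples
#' project_stock(100, flow_assumptions(2020, inflow_foreign_trained = 10),
#'               horizon = 2020:2022)
#' @export
project_stock <- function(initial_stock, flows = NULL, pipeline = NULL,
                          horizon) {
  check_scalar(initial_stock, "initial_stock", lower = 0)
  horizon <- as.integer(horizon)
  if (length(horizon) == 0 || any(diff(horizon) != 1L)) {
    abort_config("'horizon' must be a non-empty contiguous range of years")
  }
  n <- length(horizon)
  inflow <- graduates <- outflow <- stock <- numeric(n)
  prev <- initial_stock
  for (i in seq_len(n)) {
    f <- flows_for_year(flows, horizon[i])
    inflow[i] <- f[["inflow_foreign_trained"]] +
      f[["inflow_returning_domestic"]] + f[["inflow_return_from_absence"]]
    outflow[i] <- f[["outflow_emigration"]] + f[["outflow_absence"]] +
      f[["outflow_retirement_death"]]
    graduates[i] <- if (is.null(pipeline)) 0 else {
      new_graduates(pipeline, horizon[i] - pipeline$course_length)
    }
    s <- prev + inflow[i] + graduates[i] - outflow[i]
    if (s < 0) {
      warning(sprintf(
        "outflows exceed stock in %d; stock floored at zero (was %.2f)",
        horizon[i], s), call. = FALSE)
      s <- 0
    }
    stock[i] <- s
    prev <- s
  }
  out <- tibble::tibble(year = horizon, inflow = inflow,
                        graduates = graduates, outflow = outflow,
                        stock = stock)
  attr(out, "initial_stock") <- initial_stock
  class(out) <- c("stock_series", class(out))
  out
}

#' FTE provider supply from registered stock
#'
#' Registers include practitioners who are not actively practising and
#' practitioners working part-time, so the headcount stock is adjusted by the
#' participation rate and the activity rate before being reported as
#' full-time-equivalent supply:
#' `stock * participation_rate * activity_rate`.
#'
#' @param stock Headcount (vectorised; e.g. the `stock` column of a
#'   [project_stock()] result).
#' @param params A [supply_params()] object.
#' @return FTE supply, same length as `stock`.
#' @examples
#' fte_supply(1000, supply_params(0.95, 0.30, 0.50)) # 807.5
#' @export
fte_supply <- function(stock, params = supply_params()) {
  validate_supply_params(params)
  if (any(!is.finite(stock)) || any(stock < 0)) {
    abort_config("'stock' must be finite and >= 0")
  }
  stock * params$participation_rate *
    activity_rate(params$part_time_share, params$part_time_hours_fraction)
}
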