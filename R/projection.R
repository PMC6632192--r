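#' Named scenario as a set of parameter overrides
#'
#' A scenario is a named, partial override of the baseline parameter set.
#' Overrides address fields of the service times, capacity, supply, graduate
#' pipeline or flow assumptions, either as a nested list
#' (`list(times = list(minutes_emergency = 60))`) or with dotted paths
#' (`list("times.minutes_emergency" = 60)`). A flow override sets that flow
#' component for every year.
#'
#' @param name Scenario label (non-empty string).
#' @param overrides Named list of overrides (possibly empty).
#' @return An object of class `scenario_spec`.
#' @examples
#' scenario_spec("longer_visit_times",
#'               list(times = list(minutes_checkup = 30, minutes_routine = 40,
#'                                 minutes_emergency = 60)))
#' @export
scenario_spec <- function(name, overrides = list()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_config("scenario 'name' must be a non-empty string")
  }
  if (!is.list(overrides)) abort_config("'overrides' must be a list")
  structure(list(name = name, overrides = overrides),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  ov <- flatten_overrides(x$overrides)
  cat(sprintf("<scenario '%s': %d override(s)>\n", x$name, length(ov)))
  for (p in names(ov)) cat(sprintf("  %s = %g\n", p, ov[[p]]))
  invisible(x)
}

# nested override lists become dotted paths: list(times=list(a=1)) -> "times.a"
flatten_overrides <- function(overrides, prefix = NULL) {
  out <- list()
  for (nm in names(overrides)) {
    if (is.null(nm) || !nzchar(nm)) abort_config("overrides must be named")
    path <- if (is.null(prefix)) nm else paste(prefix, nm, sep = ".")
    val <- overrides[[nm]]
    if (is.list(val)) {
      out <- c(out, flatten_overrides(val, path))
    } else {
      out[[path]] <- val
    }
  }
  out
}

override_groups <- function() {
  list(times = "validate_service_times",
       capacity = "validate_capacity_params",
       supply = "validate_supply_params",
       pipeline = "validate_graduate_pipeline",
       flows = "validate_flow_assumptions")
}

#' Apply scenario overrides to a baseline parameter set
#'
#' Returns a copy of the baseline with the scenario's fields replaced; the
#' baseline object is never modified. Unknown override paths are rejected by
#' name, and each touched parameter group is re-validated, so a scenario
#' cannot produce an invalid parameter set.
#'
#' @param params A [baseline_params()] parameter set.
#' @param spec A [scenario_spec()].
#' @return A new `wp_params` object with the overrides applied.
#' @export
apply_overrides <- function(params, spec) {
  stopifnot(inherits(params, "wp_params"), inherits(spec, "scenario_spec"))
  ov <- flatten_overrides(spec$overrides)
  out <- params
  groups <- override_groups()
  touched <- character(0)
  for (path in names(ov)) {
    parts <- strsplit(path, ".", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !(parts[1] %in% names(groups))) {
      abort_config("unknown override path '%s' (known groups: %s)", path,
                   paste(names(groups), collapse = ", "))
    }
    group <- parts[1]
    field <- parts[2]
    if (group == "flows") {
      if (!(field %in% flow_components())) {
        abort_config("unknown override path '%s': no flow component '%s'",
                     path, field)
      }
      out$flows[[field]] <- ov[[path]]
    } else {
      if (is.null(out[[group]])) {
        abort_config("cannot override '%s': baseline has no %s", path, group)
      }
      if (!(field %in% names(out[[group]]))) {
        abort_config("unknown override path '%s': no field '%s' in %s",
                     path, field, group)
      }
      out[[group]][[field]] <- ov[[path]]
    }
    touched <- union(touched, group)
  }
  for (group in touched) {
    do.call(groups[[group]], list(out[[group]]))
  }
  out
}

#' Run the supply-vs-requirement projection over the planning horizon
#'
#' For every year of the horizon: project the registered stock with the
#' stock-flow recursion ([project_stock()]), convert it to FTE supply
#' ([fte_supply()]), compute the FTE requirement from the stratum visit rates
#' and the year's population ([total_visits()], [service_minutes()],
#' [fte_requirement()]), and form the supply-to-requirement ratio from the
#' unrounded FTE values. A year with zero requirement yields an `NA` ratio
#' and a warning.
#'
#' @param params A [baseline_params()] parameter set.
#' @param rates A [estimate_need_rates()] result (sex x age band).
#' @param population A [population_table()] covering the horizon.
#' @return A tibble of class `projection_result` with columns `year`,
#'   `stock`, `fte_supply`, `fte_requirement`, `ratio`.
#' @examples
#' truth <- synthetic_truth()
#' rates <- estimate_need_rates(gen_survey(truth, 5000, seed = 1))
#' pop <- gen_population(truth, horizon = 2017:2020)
#' params <- baseline_params(initial_stock = 3000, horizon = 2017:2020)
#' run_projection(params, rates, pop)
#' @export
run_projection <- function(params, rates, population) {
  stopifnot(inherits(params, "wp_params"))
  stock <- project_stock(params$initial_stock, params$flows,
                         params$pipeline, params$horizon)
  supply <- fte_supply(stock$stock, params$supply)
  capacity <- annual_capacity_minutes(params$capacity)
  requirement <- vapply(params$horizon, function(y) {
    tryCatch({
      v <- total_visits(rates, population, y)
      fte_requirement(service_minutes(v, params$times), capacity)
    }, error = function(e) {
      stop(sprintf("year %d: %s", y, conditionMessage(e)), call. = FALSE)
    })
  }, numeric(1))
  ratio <- ifelse(requirement > 0, supply / requirement, NA_real_)
  if (any(requirement <= 0)) {
    warning(sprintf("requirement is zero in %d year(s); ratio undefined there",
                    sum(requirement <= 0)), call. = FALSE)
  }
  out <- tibble::tibble(year = params$horizon, stock = stock$stock,
                        fte_supply = supply, fte_requirement = requirement,
                        ratio = ratio)
  class(out) <- c("projection_result", class(out))
  out
}

#' Compare baseline and scenario projections
#'
#' Runs the baseline parameter set and each scenario (baseline with that
#' scenario's overrides applied) over the same horizon, inputs and need
#' rates, and returns a tidy long table with one row per scenario x year.
#' Scenario runs never mutate the baseline.
#'
#' @param params Baseline [baseline_params()].
#' @param scenarios List of [scenario_spec()]s with distinct names (the name
#'   `"baseline"` is reserved).
#' @inheritParams run_projection
#' @return Tibble with columns `scenario`, `year`, `stock`, `fte_supply`,
#'   `fte_requirement`, `ratio`; baseline rows come first.
#' @seealso [default_scenarios()]
#' @export
compare_scenarios <- function(params, scenarios = list(), rates, population) {
  stopifnot(is.list(scenarios))
  for (s in scenarios) stopifnot(inherits(s, "scenario_spec"))
  nms <- vapply(scenarios, `[[`, character(1), "name")
  if (anyDuplicated(nms) || "baseline" %in% nms) {
    abort_config("scenario names must be distinct and must not be 'baseline'")
  }
  runs <- c(list(baseline = run_projection(params, rates, population)),
            stats::setNames(lapply(scenarios, function(s) {
              run_projection(apply_overrides(params, s), rates, population)
            }), nms))
  dplyr::bind_rows(lapply(names(runs), function(nm) {
    dplyr::mutate(tibble::as_tibble(runs[[nm]]), scenario = nm,
                  .before = 1)
  }))
}

#' Standard sensitivity scenarios
#'
#' The three scenario analyses exercised in reports: (1) longer per-visit
#' service times (30/40/60 minutes instead of 20/30/40), probing the
#' treatment-time assumption; (2) a child-care time adjustment in which 20%
#' of clinical time goes to patients under 15, so capacity available to the
#' modelled adult population drops to 80% of baseline; (3) both combined.
#'
#' @return Named list of three [scenario_spec()]s.
#' @export
default_scenarios <- function() {
  longer_times <- list(times = list(minutes_checkup = 30, minutes_routine = 40,
                                    minutes_emergency = 60))
  child_time <- list(capacity = list(adult_care_share = 0.8))
  list(
    longer_visit_times = scenario_spec("longer_visit_times", longer_times),
    child_care_time = scenario_spec("child_care_time", child_time),
    combined = scenario_spec("combined", c(longer_times, child_time)))
}

#' Plot the supply-to-requirement ratio by scenario
#'
#' Line chart of the FTE supply / FTE requirement ratio over the planning
#' horizon, one line per scenario. A ratio of 1 (supply meeting requirement
#' exactly) is marked.
#'
#' @param comparison A [compare_scenarios()] result.
#' @return A ggplot object.
#' @export
plot_supply_requirement_ratio <- function(comparison) {
  stopifnot(all(c("scenario", "year", "ratio") %in% names(comparison)))
  ggplot2::ggplot(comparison,
                  ggplot2::aes(x = .data$year, y = .data$ratio,
                               colour = .data$scenario)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "Year", y = "FTE supply / FTE requirement",
                  colour = "Scenario") +
    ggplot2::theme_minimal()
}
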