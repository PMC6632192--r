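#' Load and validate a run configuration
#'
#' Reads a YAML or JSON run configuration, fills every omitted parameter with
#' the baseline defaults (service times 20/30/40 min; 45 weeks; 39 h/week;
#' 90% clinical time; participation 95%; 30% part-time at 50% hours;
#' frequency mapping once/twice/three-plus to 1/2/3.5; horizon 2017--2050)
#' and validates the result against every parameter invariant, naming the
#' offending key on failure. `path = NULL` yields the pure defaults.
#'
#' Recognised top-level keys: `inputs` (`survey`, `population`,
#' `register_earlier`, `register_later` file paths), `initial_stock`,
#' `horizon` (`start`/`end`), `frequency_mapping`, `service_times`,
#' `capacity`, `supply`, `pipeline`, `flows` (list of yearly rows),
#' `scenarios` (list of `name` + `overrides`), `synth` (`n_survey`,
#' `n_register`), `seed`, `output_dir`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file, or
#'   `NULL` for defaults.
#' @return An object of class `run_config`: the [baseline_params()] set plus
#'   input paths, scenario specs, synthetic-data sizes, seed and output
#'   directory.
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) {
    list()
  } else {
    if (!file.exists(path)) abort_config("configuration file not found: %s",
                                         path)
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
    } else {
      yaml::read_yaml(path) %||% list()
    }
  }
  known <- c("inputs", "initial_stock", "horizon", "frequency_mapping",
             "service_times", "capacity", "supply", "pipeline", "flows",
             "scenarios", "synth", "seed", "output_dir")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort_config("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", "))
  }
  build <- function(ctor, values) {
    values <- values %||% list()
    bad <- setdiff(names(values), names(formals(ctor)))
    if (length(bad)) {
      abort_config("unknown field(s): %s", paste(bad, collapse = ", "))
    }
    do.call(ctor, values)
  }
  horizon <- if (is.null(raw$horizon)) 2017:2050 else {
    if (!all(c("start", "end") %in% names(raw$horizon))) {
      abort_config("'horizon' needs 'start' and 'end'")
    }
    seq(as.integer(raw$horizon$start), as.integer(raw$horizon$end))
  }
  mapping <- if (is.null(raw$frequency_mapping)) frequency_mapping() else {
    do.call(frequency_mapping, as.list(raw$frequency_mapping))
  }
  flows <- if (is.null(raw$flows)) flow_assumptions(year = horizon[1]) else {
    rows <- dplyr::bind_rows(lapply(raw$flows, tibble::as_tibble))
    build(flow_assumptions, as.list(rows))
  }
  pipeline <- if (is.null(raw$pipeline)) NULL else {
    build(graduate_pipeline, raw$pipeline)
  }
  params <- baseline_params(
    initial_stock = raw$initial_stock %||% 0,
    flows = flows, pipeline = pipeline,
    supply = build(supply_params, raw$supply),
    times = build(service_times, raw$service_times),
    capacity = build(capacity_params, raw$capacity),
    mapping = mapping, horizon = horizon)
  scenarios <- lapply(raw$scenarios %||% list(), function(s) {
    if (is.null(s$name)) abort_config("every scenario needs a 'name'")
    scenario_spec(s$name, s$overrides %||% list())
  })
  synth <- raw$synth %||% list()
  structure(
    list(params = params,
         inputs = raw$inputs %||% list(),
         scenarios = scenarios,
         synth = list(n_survey = as.integer(synth$n_survey %||% 20000L),
                      n_register = as.integer(synth$n_register %||% 500L)),
         seed = as.integer(raw$seed %||% 1L),
         output_dir = raw$output_dir %||% "."),
    class = "run_config")
}

# plain-list form used for serialisation and hashing
as_config_list <- function(config) {
  stopifnot(inherits(config, "run_config"))
  p <- config$params
  list(
    inputs = config$inputs,
    initial_stock = p$initial_stock,
    horizon = list(start = min(p$horizon), end = max(p$horizon)),
    frequency_mapping = as.list(stats::setNames(as.numeric(p$mapping),
                                                names(p$mapping))),
    service_times = unclass(p$times),
    capacity = unclass(p$capacity),
    supply = unclass(p$supply),
    pipeline = if (is.null(p$pipeline)) NULL else unclass(p$pipeline),
    flows = lapply(seq_len(nrow(p$flows)), function(i) {
      as.list(p$flows[i, ])
    }),
    scenarios = lapply(config$scenarios, function(s) {
      list(name = s$name, overrides = s$overrides)
    }),
    synth = config$synth,
    seed = config$seed,
    output_dir = config$output_dir)
}

#' Write a run configuration to YAML
#'
#' Serialises a [load_config()] object so that reloading it reproduces the
#' identical parameter set (round-trip identity).
#'
#' @param config A `run_config`.
#' @param path Output path (`.yaml`).
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  x <- as_config_list(config)
  x <- x[!vapply(x, is.null, logical(1))]
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Fingerprint of a run configuration
#'
#' Stable hash of the full parameter set, recorded in the metadata header of
#' every output file so results can be traced back to their configuration.
#'
#' @param config A `run_config`.
#' @return Hash string.
#' @export
config_hash <- function(config) {
  rlang::hash(as_config_list(config))
}

#' Read survey microdata from CSV
#'
#' One row per respondent with columns `sex` (`female`/`male`), `age_years`,
#' `natural_teeth_category`, `food_pain_problem` (logical), `visited_12m`
#' (logical), `frequency_category`, `last_visit_type` and optionally
#' `weight`. Lines starting with `#` are metadata comments.
#'
#' @param path CSV path.
#' @return Survey tibble, validated.
#' @export
read_survey_csv <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  log_info("read %d survey records from %s", nrow(x), path)
  validate_survey(x)
}

#' Read a population table from CSV
#'
#' Columns `year`, `sex`, `age_band` (labels exactly `15-44`, `45-64`,
#' `65-74`, `75+`) and `persons`.
#'
#' @param path CSV path.
#' @return A [population_table()].
#' @export
read_population_csv <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  log_info("read population table (%d rows) from %s", nrow(x), path)
  population_table(x)
}

#' Read a register snapshot from CSV
#'
#' Columns `registrant_id`, `date_registered` (ISO 8601), `year_qualified`,
#' `qualification_origin` (`domestic`/`foreign`), `practice_status`
#' (`general_practice`/`excluded`).
#'
#' @param path CSV path.
#' @param as_of_year Calendar year the snapshot refers to.
#' @return A [register_snapshot()].
#' @export
read_register_csv <- function(path, as_of_year) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE)
  log_info("read register snapshot (%d entries) from %s", nrow(x), path)
  register_snapshot(as_of_year, x)
}

#' Write a result table as CSV with a metadata header
#'
#' Prepends commented metadata lines (package version, configuration hash,
#' seed, timestamp-free for reproducibility) before the CSV body, so every
#' artefact records how it was produced. Readers in this package skip `#`
#' lines.
#'
#' @param x Data frame to write.
#' @param path Output path.
#' @param config Optional `run_config` whose hash is recorded.
#' @param seed Optional seed to record.
#' @return `path`, invisibly.
#' @export
write_result_csv <- function(x, path, config = NULL, seed = NULL) {
  header <- c(
    sprintf("# generated by oralforce %s",
            as.character(utils::packageVersion("oralforce"))),
    if (!is.null(config)) sprintf("# config_hash: %s", config_hash(config)),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
  writeLines(header, path)
  readr::write_csv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
  log_info("wrote %s (%d rows)", path, nrow(x))
  invisible(path)
}
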