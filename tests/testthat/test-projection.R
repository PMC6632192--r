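toy_params <- function(...) {
  baseline_params(initial_stock = 1000,
                  flows = flow_assumptions(2020, inflow_foreign_trained = 10),
                  horizon = 2020:2022, ...)
}

test_that("scenario overrides replace named fields and nothing else", {
  base <- toy_params()
  same <- apply_overrides(base, scenario_spec("noop"))
  expect_identical(same, base)

  sc <- scenario_spec("emerg", list(times = list(minutes_emergency = 60)))
  got <- apply_overrides(base, sc)
  expect_equal(got$times$minutes_emergency, 60)
  got$times$minutes_emergency <- base$times$minutes_emergency
  expect_identical(got, base)
  # baseline untouched
  expect_equal(base$times$minutes_emergency, 40)

  # dotted-path form is equivalent to the nested form
  dotted <- apply_overrides(base,
                            scenario_spec("emerg2",
                                          list("times.minutes_emergency" = 60)))
  expect_equal(dotted$times$minutes_emergency, 60)
})

test_that("combined scenario applies the union of its parts' overrides", {
  scs <- default_scenarios()
  base <- toy_params()
  s1 <- apply_overrides(base, scs$longer_visit_times)
  s2 <- apply_overrides(base, scs$child_care_time)
  s3 <- apply_overrides(base, scs$combined)
  expect_equal(s3$times, s1$times)
  expect_equal(s3$capacity, s2$capacity)
})

test_that("unknown or invalid override paths are rejected by name", {
  base <- toy_params()
  expect_error(apply_overrides(base, scenario_spec("x", list(foo = 1))), "foo")
  expect_error(
    apply_overrides(base, scenario_spec("x", list(times = list(bogus = 1)))),
    "bogus")
  expect_error(
    apply_overrides(base,
                    scenario_spec("x", list(supply =
                                              list(participation_rate = 2)))),
    "participation_rate")
  expect_error(
    apply_overrides(base,
                    scenario_spec("x", list(pipeline =
                                              list(intake_places = 10)))),
    "has no pipeline")
  # flow overrides apply to every year
  got <- apply_overrides(base,
                         scenario_spec("f",
                                       list(flows =
                                              list(outflow_emigration = 4))))
  expect_equal(got$flows$outflow_emigration, rep(4, nrow(got$flows)))
})

test_that("a projection year equals the manual composition of the components", {
  rates <- make_rates(tibble::tibble(
    sex = c("female", "male"), age_band = c("15-44", "65-74"),
    rate_checkup = c(0.8, 0.5), rate_routine = c(0.3, 0.4),
    rate_emergency = c(0.1, 0.2)))
  pop <- make_population(2020:2022, 5000)
  params <- toy_params()
  got <- run_projection(params, rates, pop)

  # oracle: call each module operation by hand for every year
  stock <- 1000 + 10 * (1:3)
  supply <- stock * 0.95 * activity_rate(0.30, 0.50)
  cap <- annual_capacity_minutes(capacity_params())
  req <- vapply(2020:2022, function(y) {
    fte_requirement(
      service_minutes(total_visits(rates, pop, y), service_times()), cap)
  }, numeric(1))
  expect_equal(got$stock, stock)
  expect_equal(got$fte_supply, supply)
  expect_equal(got$fte_requirement, req)
  expect_equal(got$ratio, supply / req)
})

test_that("zero requirement flags the ratio as undefined", {
  params <- toy_params()
  expect_warning(
    got <- run_projection(params, make_rates(), make_population(2020:2022, 1000)),
    "ratio undefined")
  expect_true(all(is.na(got$ratio)))
  expect_equal(got$fte_requirement, rep(0, 3))
})

test_that("scenario comparison is tidy, order-independent and non-mutating", {
  rates <- make_rates(tibble::tibble(
    sex = "female", age_band = "15-44",
    rate_checkup = 0.6, rate_routine = 0.3, rate_emergency = 0.1))
  pop <- make_population(2020:2022, 10000)
  params <- toy_params()
  params_copy <- params

  only_base <- compare_scenarios(params, list(), rates, pop)
  expect_equal(unique(only_base$scenario), "baseline")

  scs <- unname(default_scenarios())
  tab <- compare_scenarios(params, scs, rates, pop)
  expect_setequal(unique(tab$scenario),
                  c("baseline", "longer_visit_times", "child_care_time",
                    "combined"))
  expect_equal(nrow(tab), 4 * 3)

  # capacity scaled to 80% multiplies the requirement by exactly 1.25
  base_req <- tab$fte_requirement[tab$scenario == "baseline"]
  child_req <- tab$fte_requirement[tab$scenario == "child_care_time"]
  expect_equal(child_req, base_req * 1.25, tolerance = 1e-12)

  # permuting the specs yields the same content
  tab_perm <- compare_scenarios(params, rev(scs), rates, pop)
  expect_equal(dplyr::arrange(tab_perm, scenario, year),
               dplyr::arrange(tab, scenario, year))

  # scenario runs never mutate the baseline parameters
  expect_identical(params, params_copy)
  rerun <- compare_scenarios(params, list(), rates, pop)
  expect_identical(rerun, only_base)

  expect_error(compare_scenarios(params, list(scs[[1]], scs[[1]]), rates, pop),
               "distinct")
})
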