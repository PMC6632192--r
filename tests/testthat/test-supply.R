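test_that("activity rate averages full-time and part-time hours", {
  expect_equal(activity_rate(0.30, 0.50), 0.85)
  expect_equal(activity_rate(0, 0.3), 1)
  expect_equal(activity_rate(1, 1), 1)
  expect_equal(activity_rate(1, 0.5), 0.5)
  expect_error(activity_rate(1.2, 0.5), "part_time_share")
  expect_error(activity_rate(0.5, -0.1), "part_time_hours_fraction")
})

test_that("graduate output applies non-progression, attrition and employment share", {
  expect_equal(new_graduates(graduate_pipeline(100, 0.10, 0.05, 0.80)), 68.4)
  expect_equal(new_graduates(graduate_pipeline(100, attrition_rate = 1)), 0)
  expect_equal(new_graduates(graduate_pipeline(0)), 0)
  expect_error(graduate_pipeline(100, nonprogression_y2 = 1.5),
               "nonprogression_y2")
  expect_error(graduate_pipeline(-1), "intake_places")
})

test_that("FTE supply scales stock by participation and activity", {
  expect_equal(fte_supply(1000, supply_params(0.95, 0.30, 0.50)), 807.5)
  expect_equal(fte_supply(123.4, supply_params(1, 0, 0.5)), 123.4)
  expect_equal(fte_supply(0, supply_params()), 0)
  expect_error(fte_supply(-1, supply_params()), "stock")
})

test_that("FTE supply never exceeds stock and is monotone in its rates", {
  stocks <- c(0, 10, 3053, 1e5)
  for (p in seq(0, 1, by = 0.25)) {
    for (h in seq(0, 1, by = 0.25)) {
      expect_true(all(fte_supply(stocks, supply_params(p, 0.4, h)) <= stocks))
    }
  }
  ps <- seq(0, 1, by = 0.1)
  sup_p <- vapply(ps, function(p) fte_supply(100, supply_params(p, 0.3, 0.5)),
                  numeric(1))
  sup_h <- vapply(ps, function(h) fte_supply(100, supply_params(0.9, 0.3, h)),
                  numeric(1))
  expect_true(all(diff(sup_p) >= 0))
  expect_true(all(diff(sup_h) >= 0))
})

test_that("stock projection follows the stock-flow recursion", {
  # zero flows: stock stays at the initial register count
  const <- project_stock(3053, horizon = 2017:2050)
  expect_equal(const$stock, rep(3053, 34))

  # net +10/yr for 3 years
  flows <- flow_assumptions(2020, inflow_foreign_trained = 10)
  got <- project_stock(100, flows, horizon = 2020:2022)
  expect_equal(got$stock, c(110, 120, 130))

  # graduates from the cohort entering in y arrive at the end of y + course
  pipe <- graduate_pipeline(100, 0.10, 0.05, 0.80)
  with_grads <- project_stock(100, pipeline = pipe, horizon = 2020:2022)
  expect_equal(with_grads$stock, 100 + 68.4 * (1:3))
})

test_that("stock is floored at zero with a warning when outflows exceed it", {
  flows <- flow_assumptions(2020, outflow_emigration = 50)
  w <- capture_warnings(got <- project_stock(80, flows, horizon = 2020:2022))
  expect_length(w, 2) # one warning per floored year
  expect_match(w, "floored", all = TRUE)
  expect_equal(got$stock, c(30, 0, 0))
})

test_that("missing flow years carry forward; years before the table error", {
  flows <- flow_assumptions(c(2020, 2022),
                            inflow_foreign_trained = c(5, 1),
                            outflow_emigration = c(0, 3))
  got <- project_stock(100, flows, horizon = 2020:2024)
  # 2021 inherits 2020 (+5); 2023-24 inherit 2022 (-2)
  expect_equal(got$stock, c(105, 110, 108, 106, 104))
  expect_error(project_stock(100, flows, horizon = 2019:2021),
               "no flow assumptions for year 2019")
})

test_that("stock conservation holds to 1e-9 across a 30-year projection", {
  flows <- flow_assumptions(2017:2046,
                            inflow_foreign_trained = runif(30, 0, 40),
                            inflow_returning_domestic = runif(30, 0, 10),
                            inflow_return_from_absence = runif(30, 0, 8),
                            outflow_emigration = runif(30, 0, 30),
                            outflow_absence = runif(30, 0, 12),
                            outflow_retirement_death = runif(30, 0, 45))
  pipe <- graduate_pipeline(72, 0.08, 0.03, 0.82)
  got <- project_stock(3053, flows, pipe, 2017:2046)
  prev <- c(attr(got, "initial_stock"), got$stock[-30])
  expect_equal(got$stock - prev, got$inflow + got$graduates - got$outflow,
               tolerance = 1e-9)
})

test_that("reversed, inflow/outflow-swapped flows return to the initial stock", {
  flows <- flow_assumptions(2020:2024,
                            inflow_foreign_trained = c(12, 0, 7, 3, 9),
                            outflow_emigration = c(4, 8, 0, 6, 2))
  fwd <- project_stock(500, flows, horizon = 2020:2024)
  back_flows <- flow_assumptions(2020:2024,
                                 inflow_foreign_trained = rev(c(4, 8, 0, 6, 2)),
                                 outflow_emigration = rev(c(12, 0, 7, 3, 9)))
  back <- project_stock(fwd$stock[5], back_flows, horizon = 2020:2024)
  expect_equal(back$stock[5], 500)
})

test_that("register snapshots reject invalid entries", {
  expect_error(make_register(2017, c("A", "A")), "duplicate registrant_id")
  expect_error(
    register_snapshot(2017, tibble::tibble(
      registrant_id = "A", date_registered = as.Date("2000-01-01"),
      year_qualified = 2005L, qualification_origin = "domestic",
      practice_status = "general_practice")),
    "year_qualified later")
  expect_error(make_register(2017, "A", origin = "elsewhere"),
               "qualification_origin")
})

test_that("register diffing classifies inflows and counts outflows", {
  a <- make_register(2017, c("A", "B"))
  # identical snapshots -> all flows zero
  same <- diff_registers(a, make_register(2018, c("A", "B")))
  expect_true(all(same$counts == 0))

  # {A,B} -> {B, C(foreign)}: one foreign-trained inflow, one outflow
  later <- make_register(2018, c("B", "C"), origin = c("domestic", "foreign"))
  d <- diff_registers(a, later)
  expect_equal(unname(d$counts["inflow_foreign_trained"]), 1)
  expect_equal(unname(d$counts["outflow_unclassified"]), 1)
  expect_equal(d$total_inflow - d$total_outflow,
               nrow(later$entries) - nrow(a$entries))

  # domestic entrant qualified after the earlier snapshot is a new graduate;
  # qualified before it, a returning-domestic registrant
  grad <- make_register(2018, c("A", "B", "G"), year_qualified = 2018L)
  expect_equal(unname(diff_registers(a, grad)$counts["inflow_graduates"]), 1)
  ret <- make_register(2018, c("A", "B", "R"), year_qualified = 1995L)
  expect_equal(
    unname(diff_registers(a, ret)$counts["inflow_returning_domestic"]), 1)

  expect_error(diff_registers(later, a), "must predate")
})

test_that("retirement heuristic splits outflows by qualification age", {
  earlier <- make_register(2017, c("OLD", "NEW"),
                           year_qualified = c(1970L, 2010L))
  later <- make_register(2018, character(0))
  d <- diff_registers(earlier, later, retirement_heuristic = TRUE)
  expect_equal(unname(d$counts["outflow_retirement_est"]), 1)
  expect_equal(unname(d$counts["outflow_unclassified"]), 1)
})
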