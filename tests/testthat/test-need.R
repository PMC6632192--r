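test_that("age bands partition 15+ with inclusive upper bounds at 44/64/74", {
  expect_equal(as.character(age_band(c(15, 44, 45, 64, 65, 74, 75, 99))),
               c("15-44", "15-44", "45-64", "45-64", "65-74", "65-74",
                 "75+", "75+"))
  expect_true(is.na(age_band(14)))
})

test_that("stratum assignment filters under-15s and incomplete records with a log", {
  records <- dplyr::bind_rows(
    make_survey_row("female", 44, TRUE, "once", "checkup_exam_cleaning"),
    make_survey_row("male", 75, FALSE),
    make_survey_row("female", 65, FALSE),
    make_survey_row("male", 12, FALSE),             # under age
    make_survey_row("female", 30, TRUE))            # visitor missing freq/type
  expect_message(got <- assign_stratum(records), "aged under 15")
  expect_equal(nrow(got), 3)
  expect_equal(as.character(got$age_band), c("15-44", "75+", "65-74"))
})

test_that("health-status key combines teeth category and pain indicator", {
  rec <- make_survey_row("female", 50, FALSE)
  rec$natural_teeth_category <- "6_plus_missing"
  rec$food_pain_problem <- TRUE
  got <- assign_stratum(rec, use_health_status = TRUE)
  expect_equal(got$health_status, "teeth:6_plus_missing|pain:TRUE")
})

test_that("per-record visits follow the frequency mapping, zero for non-visitors", {
  mapping <- frequency_mapping(once = 1, twice = 2, three_or_more = 3.5)
  expect_equal(visits_for_record(FALSE, NA, mapping), 0)
  expect_equal(visits_for_record(TRUE, "twice", mapping), 2)
  expect_equal(visits_for_record(TRUE, "three_or_more", mapping), 3.5)
  expect_equal(visits_for_record(c(TRUE, FALSE, TRUE), c("once", NA, "twice"),
                                 mapping), c(1, 0, 2))
  expect_error(visits_for_record(TRUE, "weekly", mapping), "weekly")
})

test_that("frequency mappings must be named, non-negative and non-decreasing", {
  expect_equal(unname(frequency_mapping()[["three_or_more"]]), 3.5)
  expect_error(frequency_mapping(once = 2, twice = 1), "non-decreasing")
  expect_error(frequency_mapping(1, 2), "named")
  expect_error(frequency_mapping(once = -1, twice = 2), ">= 0")
})

test_that("need rates match a hand count on a two-respondent stratum", {
  records <- dplyr::bind_rows(
    make_survey_row("female", 30, TRUE, "twice", "checkup_exam_cleaning"),
    make_survey_row("female", 40, FALSE))
  rates <- suppressMessages(estimate_need_rates(records))
  row <- rates[rates$sex == "female" & rates$age_band == "15-44", ]
  expect_equal(row$rate_total, 1.0)
  expect_equal(row$rate_checkup, 1.0)
  expect_equal(row$rate_routine, 0)
  expect_equal(row$rate_emergency, 0)
  expect_equal(row$n_respondents, 2L)
  # empty strata are flagged undefined, never silently zeroed
  expect_equal(nrow(rates), 8)
  expect_false(any(rates$defined[rates$n_respondents == 0]))
  expect_true(all(is.na(rates$rate_total[!rates$defined])))
})

test_that("all-non-visitor strata get zero rates", {
  records <- dplyr::bind_rows(
    make_survey_row("male", 20, FALSE),
    make_survey_row("male", 25, FALSE))
  rates <- suppressMessages(estimate_need_rates(records))
  row <- rates[rates$sex == "male" & rates$age_band == "15-44", ]
  expect_equal(row$rate_total, 0)
  expect_equal(row$rate_checkup + row$rate_routine + row$rate_emergency, 0)
})

test_that("type-specific rates sum to the stratum total", {
  survey <- gen_survey(synthetic_truth(), n = 4000, seed = 11)
  rates <- suppressMessages(estimate_need_rates(survey))
  expect_equal(rates$rate_checkup + rates$rate_routine + rates$rate_emergency,
               rates$rate_total, tolerance = 1e-9)
})

test_that("estimates are invariant to record order and weight scaling", {
  survey <- gen_survey(synthetic_truth(), n = 3000, seed = 5)
  survey$weight <- runif(nrow(survey), 0.5, 2)
  base <- suppressMessages(estimate_need_rates(survey, use_weights = TRUE))

  shuffled <- survey[sample.int(nrow(survey)), ]
  perm <- suppressMessages(estimate_need_rates(shuffled, use_weights = TRUE))
  expect_equal(tibble::as_tibble(perm), tibble::as_tibble(base))

  survey$weight <- survey$weight * 7
  scaled <- suppressMessages(estimate_need_rates(survey, use_weights = TRUE))
  expect_equal(scaled$rate_total, base$rate_total, tolerance = 1e-12)
  expect_equal(scaled$rate_checkup, base$rate_checkup, tolerance = 1e-12)
})

test_that("estimator is consistent: error shrinks roughly as 1/sqrt(n)", {
  truth <- synthetic_truth()
  tr <- true_need_rates(truth)
  rmse <- vapply(c(500, 5000, 50000), function(n) {
    est <- suppressMessages(
      estimate_need_rates(gen_survey(truth, n, seed = 42)))
    est <- dplyr::inner_join(tibble::as_tibble(est), tr,
                             by = c("sex", "age_band"))
    sqrt(mean((est$rate_total.x - est$rate_total.y)^2))
  }, numeric(1))
  expect_true(all(diff(rmse) < 0))
  # a 100-fold increase in n should shrink the RMSE by about 10; allow slack
  expect_gt(rmse[1] / rmse[3], 3)
})

test_that("bootstrap intervals are reproducible and degenerate at B = 1", {
  survey <- gen_survey(synthetic_truth(), n = 800, seed = 3)
  a <- suppressMessages(bootstrap_need_rates(survey, B = 25, seed = 9))
  b <- suppressMessages(bootstrap_need_rates(survey, B = 25, seed = 9))
  expect_equal(a, b)
  expect_true(all(a$lower <= a$upper))

  one <- suppressMessages(bootstrap_need_rates(survey, B = 1, seed = 9))
  expect_equal(one$lower, one$upper)
  expect_error(suppressMessages(bootstrap_need_rates(survey, B = 0, seed = 9)),
               "'B'")
})

test_that("bootstrap intervals cover the true stratum rates at near-nominal rates", {
  truth <- synthetic_truth()
  tr <- true_need_rates(truth)
  covered <- total <- 0L
  withr::with_seed(2024, {
    for (rep in 1:30) {
      survey <- gen_survey(truth, n = 2000, seed = sample.int(1e6, 1))
      ci <- suppressMessages(bootstrap_need_rates(survey, B = 200,
                                                  seed = sample.int(1e6, 1)))
      ci <- ci[ci$measure == "rate_total", ]
      key <- paste(tr$sex, tr$age_band, sep = " / ")
      truth_rate <- tr$rate_total[match(ci$stratum, key)]
      covered <- covered + sum(ci$lower <= truth_rate & truth_rate <= ci$upper)
      total <- total + nrow(ci)
    }
  })
  expect_gte(covered / total, 0.90)
})
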