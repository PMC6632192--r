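# shared fixture builders; everything is constructed in code at test time

SEXES <- c("female", "male")
BANDS <- c("15-44", "45-64", "65-74", "75+")

stratum_grid <- function() {
  tidyr::expand_grid(sex = factor(SEXES, SEXES),
                     age_band = factor(BANDS, BANDS))
}

# a need_rates object with given per-stratum type rates; unspecified strata
# get zero rates (defined) so toy populations can be fed through total_visits
make_rates <- function(df = NULL) {
  rates <- stratum_grid()
  rates$rate_checkup <- rates$rate_routine <- rates$rate_emergency <- 0
  if (!is.null(df)) {
    for (i in seq_len(nrow(df))) {
      sel <- rates$sex == df$sex[i] & rates$age_band == df$age_band[i]
      for (col in intersect(names(df),
                            c("rate_checkup", "rate_routine",
                              "rate_emergency"))) {
        rates[[col]][sel] <- df[[col]][i]
      }
    }
  }
  rates$rate_total <- rates$rate_checkup + rates$rate_routine +
    rates$rate_emergency
  rates$n_respondents <- 100L
  rates$effective_n <- 100
  rates$defined <- TRUE
  class(rates) <- c("need_rates", class(rates))
  rates
}

# constant population table: `persons` per stratum, same every year
make_population <- function(years, persons = 1000) {
  pop <- tidyr::expand_grid(year = as.integer(years), stratum_grid())
  pop$persons <- persons
  population_table(pop)
}

make_survey_row <- function(sex, age, visited, freq = NA_character_,
                            type = NA_character_, weight = 1) {
  tibble::tibble(sex = sex, age_years = age,
                 natural_teeth_category = "all_natural",
                 food_pain_problem = FALSE, visited_12m = visited,
                 frequency_category = freq, last_visit_type = type,
                 weight = weight)
}

make_register <- function(as_of_year, ids, origin = "domestic",
                          year_qualified = 2000L) {
  register_snapshot(as_of_year, tibble::tibble(
    registrant_id = ids,
    date_registered = as.Date(sprintf("%d-01-15", as_of_year)),
    year_qualified = rep_len(year_qualified, length(ids)),
    qualification_origin = rep_len(origin, length(ids)),
    practice_status = "general_practice"))
}

# moments of the per-record visit count V = Bernoulli(p) * count(category)
# under the synthetic truth, used for Monte-Carlo error bounds
truth_visit_moments <- function(truth, mapping = frequency_mapping()) {
  s <- truth$strata
  m <- unname(mapping[c("once", "twice", "three_or_more")])
  fp <- as.matrix(s[, c("f_once", "f_twice", "f_three")])
  ec1 <- drop(fp %*% m)
  ec2 <- drop(fp %*% m^2)
  tibble::tibble(sex = s$sex, age_band = s$age_band,
                 mean = s$p_visit * ec1,
                 var = s$p_visit * ec2 - (s$p_visit * ec1)^2)
}
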