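FREQ_LEVELS <- c("once", "twice", "three_or_more")
TEETH_LEVELS <- c("all_natural", "1_5_missing", "6_plus_missing",
                  "none_natural")

#' Ground-truth parameters for the synthetic-data generators
#'
#' Defines the data-generating process behind [gen_survey()],
#' [gen_population()] and [gen_register_pair()]: per-stratum visit
#' participation probabilities, frequency and visit-type distributions,
#' oral-health-status distributions, base population counts with annual
#' growth rates, and the flows planted between the two register snapshots.
#' Every generated dataset is a pure function of this truth record, its size
#' and a seed, so estimator output can be checked against known parameters.
#'
#' The defaults describe a small European country loosely: eight sex x
#' age-band strata, visit participation between 0.40 and 0.70 rising with age
#' then dropping in the oldest band, a check-up-heavy visit-type mix, an
#' adult population of about 3.7 million growing faster in the older bands.
#' They are entirely synthetic and claim no fidelity to any real register or
#' survey.
#'
#' @param strata Optional tibble overriding the default stratum table
#'   (columns `sex`, `age_band`, `mix`, `p_visit`, `f_once`, `f_twice`,
#'   `f_three`, `t_checkup`, `t_routine`, `t_emergency`, `pain_prob`,
#'   `base_pop`, `growth`).
#' @param teeth_probs Distribution over natural-teeth categories
#'   (named, sums to 1).
#' @param register List with the register-pair design: `year_earlier`,
#'   `year_later`, planted `inflow_graduates`, `inflow_foreign_trained`,
#'   `inflow_returning_domestic` and `outflow` counts.
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(strata = NULL, teeth_probs = NULL,
                            register = NULL) {
  if (is.null(strata)) {
    strata <- tibble::tibble(
      sex = rep(SEX_LEVELS, each = 4),
      age_band = rep(AGE_BAND_LEVELS, times = 2),
      mix = c(0.265, 0.155, 0.050, 0.036, 0.260, 0.150, 0.048, 0.036),
      p_visit = c(0.55, 0.65, 0.70, 0.50, 0.45, 0.55, 0.60, 0.40),
      f_once = c(0.50, 0.45, 0.45, 0.55, 0.55, 0.50, 0.50, 0.60),
      f_twice = c(0.32, 0.35, 0.35, 0.30, 0.30, 0.33, 0.33, 0.27),
      f_three = c(0.18, 0.20, 0.20, 0.15, 0.15, 0.17, 0.17, 0.13),
      t_checkup = c(0.62, 0.58, 0.55, 0.50, 0.58, 0.55, 0.52, 0.48),
      t_routine = c(0.28, 0.30, 0.32, 0.34, 0.30, 0.32, 0.34, 0.36),
      t_emergency = c(0.10, 0.12, 0.13, 0.16, 0.12, 0.13, 0.14, 0.16),
      pain_prob = c(0.12, 0.16, 0.20, 0.25, 0.12, 0.16, 0.20, 0.25),
      base_pop = c(1010000, 560000, 175000, 115000,
                   1000000, 545000, 160000, 80000),
      growth = c(0.002, 0.008, 0.015, 0.020, 0.002, 0.008, 0.015, 0.020))
  }
  strata <- tibble::as_tibble(strata)
  teeth_probs <- teeth_probs %||%
    c(all_natural = 0.45, `1_5_missing` = 0.35, `6_plus_missing` = 0.15,
      none_natural = 0.05)
  register <- register %||%
    list(year_earlier = 2017L, year_later = 2018L,
         inflow_graduates = 30L, inflow_foreign_trained = 12L,
         inflow_returning_domestic = 5L, outflow = 40L)

  check_dist <- function(p, what) {
    if (any(!is.finite(p)) || any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort_config("%s must be a probability distribution summing to 1", what)
    }
  }
  check_dist(strata$mix, "stratum mix")
  check_dist(teeth_probs, "teeth category distribution")
  for (i in seq_len(nrow(strata))) {
    check_dist(unlist(strata[i, c("f_once", "f_twice", "f_three")]),
               sprintf("frequency distribution (stratum %d)", i))
    check_dist(unlist(strata[i, c("t_checkup", "t_routine", "t_emergency")]),
               sprintf("visit-type distribution (stratum %d)", i))
  }
  if (any(strata$p_visit < 0 | strata$p_visit > 1) ||
      any(strata$pain_prob < 0 | strata$pain_prob > 1)) {
    abort_config("participation and pain probabilities must lie in [0, 1]")
  }
  if (any(!is.finite(strata$growth)) || any(strata$base_pop < 0)) {
    abort_config("population base counts must be >= 0 and growth rates finite")
  }
  structure(list(strata = strata, teeth_probs = teeth_probs,
                 register = register),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic truth: %d strata, base population %.0f>\n",
              nrow(x$strata), sum(x$strata$base_pop)))
  invisible(x)
}

#' True per-capita visit rates implied by a synthetic truth
#'
#' Analytic stratum rates of the data-generating process:
#' `total = p_visit x sum(freq_prob x visit_count)`, split by the visit-type
#' distribution. These are the parameters [estimate_need_rates()] should
#' recover from [gen_survey()] output.
#'
#' @param truth A [synthetic_truth()].
#' @param mapping The [frequency_mapping()] assigning visit counts to the
#'   frequency categories.
#' @return Tibble with `sex`, `age_band`, `rate_checkup`, `rate_routine`,
#'   `rate_emergency`, `rate_total`.
#' @export
true_need_rates <- function(truth, mapping = frequency_mapping()) {
  stopifnot(inherits(truth, "synthetic_truth"))
  s <- truth$strata
  m <- unname(mapping[FREQ_LEVELS])
  total <- s$p_visit * (s$f_once * m[1] + s$f_twice * m[2] + s$f_three * m[3])
  tibble::tibble(
    sex = factor(s$sex, SEX_LEVELS),
    age_band = factor(s$age_band, AGE_BAND_LEVELS),
    rate_checkup = total * s$t_checkup,
    rate_routine = total * s$t_routine,
    rate_emergency = total * s$t_emergency,
    rate_total = total)
}

age_range_for_band <- function(band) {
  switch(as.character(band),
         "15-44" = 15:44, "45-64" = 45:64, "65-74" = 65:74, "75+" = 75:90)
}

#' Generate synthetic survey microdata
#'
#' Draws `n` respondents from the truth's stratum mix; within a stratum, the
#' visit indicator is Bernoulli with the stratum participation probability,
#' and frequency category, last visit type, natural-teeth category and
#' food/pain problem follow the truth's categorical distributions.
#' Non-visitors carry `NA` frequency and visit type. Byte-identical output
#' for identical `(truth, n, seed)`.
#'
#' @param truth A [synthetic_truth()].
#' @param n Number of respondents (>= 1).
#' @param seed Integer seed (an independent stream is derived from it, so
#'   other generators using the same seed are unaffected).
#' @return Survey tibble with columns `sex`, `age_years`,
#'   `natural_teeth_category`, `food_pain_problem`, `visited_12m`,
#'   `frequency_category`, `last_visit_type`.
#' @export
gen_survey <- function(truth, n, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_scalar(n, "n", lower = 1, integerish = TRUE)
  s <- truth$strata
  with_seed(derive_seed(seed, 1L), {
    si <- sample.int(nrow(s), n, replace = TRUE, prob = s$mix)
    age <- vapply(si, function(i) {
      r <- age_range_for_band(s$age_band[i])
      r[sample.int(length(r), 1)]
    }, integer(1))
    visited <- rbinom(n, 1, s$p_visit[si]) == 1
    freq <- rep(NA_character_, n)
    type <- rep(NA_character_, n)
    pain <- rbinom(n, 1, s$pain_prob[si]) == 1
    teeth <- sample(names(truth$teeth_probs), n, replace = TRUE,
                    prob = truth$teeth_probs)
    for (i in seq_len(nrow(s))) {
      sel <- which(si == i & visited)
      if (length(sel)) {
        freq[sel] <- sample(FREQ_LEVELS, length(sel), replace = TRUE,
                            prob = unlist(s[i, c("f_once", "f_twice",
                                                 "f_three")]))
        type[sel] <- sample(VISIT_TYPES, length(sel), replace = TRUE,
                            prob = unlist(s[i, c("t_checkup", "t_routine",
                                                 "t_emergency")]))
      }
    }
    tibble::tibble(
      sex = s$sex[si], age_years = age, natural_teeth_category = teeth,
      food_pain_problem = pain, visited_12m = visited,
      frequency_category = freq, last_visit_type = type)
  })
}

#' Generate a synthetic population projection table
#'
#' Deterministic compound growth from the truth's base counts:
#' `persons(stratum, t) = base(stratum) x (1 + growth(stratum))^(t - base_year)`.
#'
#' @param truth A [synthetic_truth()].
#' @param horizon Integer vector of years to tabulate.
#' @param base_year Year the base counts refer to (default: first horizon
#'   year).
#' @return A [population_table()].
#' @export
gen_population <- function(truth, horizon, base_year = min(horizon)) {
  stopifnot(inherits(truth, "synthetic_truth"))
  horizon <- as.integer(horizon)
  s <- truth$strata
  out <- tidyr::expand_grid(year = horizon,
                            idx = seq_len(nrow(s)))
  out$sex <- s$sex[out$idx]
  out$age_band <- s$age_band[out$idx]
  out$persons <- s$base_pop[out$idx] *
    (1 + s$growth[out$idx])^(out$year - base_year)
  out$idx <- NULL
  population_table(out)
}

make_register_entries <- function(ids, reg_year, year_qualified, origin) {
  tibble::tibble(
    registrant_id = ids,
    date_registered = as.Date(sprintf("%d-06-15", reg_year)),
    year_qualified = as.integer(year_qualified),
    qualification_origin = origin,
    practice_status = "general_practice")
}

#' Generate a pair of register snapshots with planted flows
#'
#' Builds an earlier snapshot of `n0` registrants, then constructs the later
#' snapshot by removing the planted number of outflow registrants and adding
#' the planted inflows: new domestic graduates (qualified in the later year),
#' foreign-trained registrants, and returning domestic registrants qualified
#' before the earlier snapshot. [diff_registers()] on the pair recovers the
#' planted counts exactly.
#'
#' @param truth A [synthetic_truth()]; the `register` element holds the
#'   snapshot years and planted flow counts.
#' @param n0 Size of the earlier register (planted outflows must not exceed
#'   it).
#' @param seed Integer seed (independent stream).
#' @return List with `earlier` and `later` [register_snapshot()]s and
#'   `planted`, the named vector of true flow counts.
#' @export
gen_register_pair <- function(truth, n0, seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  check_scalar(n0, "n0", lower = 1, integerish = TRUE)
  r <- truth$register
  if (r$outflow > n0) {
    abort_config("planted outflows (%d) exceed register size (%d)",
                 r$outflow, n0)
  }
  with_seed(derive_seed(seed, 3L), {
    yq <- sample(seq(r$year_earlier - 40L, r$year_earlier - 1L), n0,
                 replace = TRUE)
    reg_year <- pmin(yq + sample(0:3, n0, replace = TRUE), r$year_earlier)
    origin <- sample(c("domestic", "foreign"), n0, replace = TRUE,
                     prob = c(0.85, 0.15))
    earlier_entries <- make_register_entries(sprintf("D%05d", seq_len(n0)),
                                             reg_year, yq, origin)
    out_ids <- sample(earlier_entries$registrant_id, r$outflow)

    grads <- make_register_entries(
      sprintf("G%05d", seq_len(r$inflow_graduates)),
      r$year_later, r$year_later, "domestic")
    foreign <- make_register_entries(
      sprintf("F%05d", seq_len(r$inflow_foreign_trained)),
      r$year_later,
      sample(seq(r$year_earlier - 20L, r$year_earlier), r$inflow_foreign_trained,
             replace = TRUE),
      "foreign")
    returning <- make_register_entries(
      sprintf("R%05d", seq_len(r$inflow_returning_domestic)),
      r$year_later,
      sample(seq(r$year_earlier - 25L, r$year_earlier - 2L),
             r$inflow_returning_domestic, replace = TRUE),
      "domestic")

    later_entries <- dplyr::bind_rows(
      earlier_entries[!(earlier_entries$registrant_id %in% out_ids), ],
      grads, foreign, returning)
    list(
      earlier = register_snapshot(r$year_earlier, earlier_entries),
      later = register_snapshot(r$year_later, later_entries),
      planted = c(inflow_graduates = r$inflow_graduates,
                  inflow_foreign_trained = r$inflow_foreign_trained,
                  inflow_returning_domestic = r$inflow_returning_domestic,
                  outflow = r$outflow))
  })
}
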