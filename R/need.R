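AGE_BAND_LEVELS <- c("15-44", "45-64", "65-74", "75+")
SEX_LEVELS <- c("female", "male")
VISIT_TYPES <- c("checkup_exam_cleaning", "routine_treatment",
                 "emergency_treatment")

#' Age band of the planning strata
#'
#' Assigns ages to the four planning age bands 15--44, 45--64, 65--74 and 75+
#' (bounds inclusive at 44/64/74). Ages below 15 map to `NA`: the model covers
#' the adult population only.
#'
#' @param age_years Integer ages (vectorised).
#' @return Factor with levels `"15-44"`, `"45-64"`, `"65-74"`, `"75+"`.
#' @export
age_band <- function(age_years) {
  cut(age_years, breaks = c(15, 45, 65, 75, Inf), right = FALSE,
      labels = AGE_BAND_LEVELS)
}

# coerce and sanity-check survey microdata; core fields must be present and
# visitors must carry frequency and last-visit type
validate_survey <- function(records, use_weights = FALSE) {
  records <- tibble::as_tibble(records)
  needed <- c("sex", "age_years", "visited_12m")
  missing <- setdiff(needed, names(records))
  if (length(missing)) {
    abort_config("survey records lack column(s): %s",
                 paste(missing, collapse = ", "))
  }
  bad_sex <- setdiff(unique(records$sex[!is.na(records$sex)]), SEX_LEVELS)
  if (length(bad_sex)) {
    abort_config("unknown sex value(s): %s", paste(bad_sex, collapse = ", "))
  }
  if (!is.logical(records$visited_12m)) {
    abort_config("'visited_12m' must be logical")
  }
  if (use_weights) {
    if (is.null(records$weight)) {
      abort_config("weighted estimation requested but no 'weight' column")
    }
    if (any(!is.finite(records$weight)) || any(records$weight <= 0)) {
      abort_config("'weight' must be finite and > 0")
    }
  }
  records
}

#' Assign survey respondents to planning strata
#'
#' Adds the stratum key (sex, age band and optionally oral health status) to
#' survey microdata. Respondents younger than 15 fall outside the modelled
#' population and are removed with a logged count, as are records missing a
#' core field (sex, age, visit indicator, or frequency/type for a visitor).
#'
#' @param records Survey microdata, one row per respondent (see
#'   [read_survey_csv()] for the expected columns).
#' @param use_health_status If `TRUE`, append a `health_status` key combining
#'   the natural-teeth category and the food/pain problem indicator.
#' @return The filtered records with `age_band` (and optionally
#'   `health_status`) columns added.
#' @export
assign_stratum <- function(records, use_health_status = FALSE) {
  records <- validate_survey(records)
  n0 <- nrow(records)
  core <- c("sex", "age_years", "visited_12m")
  if (use_health_status) {
    core <- c(core, "natural_teeth_category", "food_pain_problem")
  }
  complete <- stats::complete.cases(records[, core])
  visitor_bad <- records$visited_12m & !is.na(records$visited_12m) &
    (is.na(records$frequency_category) | is.na(records$last_visit_type))
  keep <- complete & !visitor_bad
  if (any(!keep)) {
    log_info("dropped %d of %d records with missing core fields",
             sum(!keep), n0)
    records <- records[keep, , drop = FALSE]
  }
  underage <- records$age_years < 15
  if (any(underage)) {
    log_info("dropped %d respondents aged under 15 (outside the modelled population)",
             sum(underage))
    records <- records[!underage, , drop = FALSE]
  }
  records$sex <- factor(records$sex, levels = SEX_LEVELS)
  records$age_band <- age_band(records$age_years)
  if (use_health_status) {
    records$health_status <- paste0("teeth:", records$natural_teeth_category,
                                    "|pain:", records$food_pain_problem)
  }
  records
}

#' Annual visits implied by one survey response
#'
#' A respondent who did not visit the dentist in the previous 12 months
#' contributes zero visits; a visitor contributes the visit count the
#' [frequency_mapping()] assigns to their frequency category.
#'
#' @param visited_12m Logical, visited the dentist in the last 12 months.
#' @param frequency_category Frequency category (character/factor); ignored
#'   for non-visitors.
#' @param mapping A [frequency_mapping()].
#' @return Numeric visits per year, same length as the inputs.
#' @examples
#' visits_for_record(c(FALSE, TRUE), c(NA, "twice"))
#' @export
visits_for_record <- function(visited_12m, frequency_category,
                              mapping = frequency_mapping()) {
  stopifnot(is.logical(visited_12m))
  out <- numeric(length(visited_12m))
  idx <- which(visited_12m)
  if (length(idx)) {
    f <- as.character(frequency_category[idx])
    unknown <- unique(f[!(f %in% names(mapping))])
    if (length(unknown)) {
      abort_config("frequency category not in mapping: %s",
                   paste(ifelse(is.na(unknown), "<missing>", unknown),
                         collapse = ", "))
    }
    out[idx] <- unname(mapping[f])
  }
  out
}

#' Estimate per-capita annual visit rates by stratum
#'
#' For each sex x age-band stratum (optionally further split by oral health
#' status) the per-capita annual visit rate is the (weighted) mean of the
#' visit counts implied by each respondent's participation and frequency
#' answers. The total rate is then split across the three visit types in
#' proportion to the (weighted) distribution of the last visit's type among
#' the stratum's visitors, so the type-specific rates sum exactly to the
#' total. Strata with no respondents are retained in the output with
#' `defined = FALSE` and `NA` rates rather than silently zero-filled.
#'
#' @param records Survey microdata (see [read_survey_csv()]).
#' @param mapping A [frequency_mapping()].
#' @param use_weights Use the `weight` column (default unweighted).
#' @param use_health_status Stratify additionally by health status. Rates used
#'   for the provider-requirement calculation must aggregate over health
#'   status (population projections carry no oral-health dimension), so leave
#'   this `FALSE` for [run_projection()] inputs.
#' @return A tibble of class `need_rates` with one row per stratum: the key
#'   columns, respondent counts (`n_respondents`, Kish `effective_n`),
#'   per-capita rates by type (`rate_checkup`, `rate_routine`,
#'   `rate_emergency`), their sum `rate_total` and the `defined` flag. The
#'   mapping and weighting choice are carried in attributes.
#' @examples
#' survey <- gen_survey(synthetic_truth(), n = 2000, seed = 1)
#' estimate_need_rates(survey)
#' @export
estimate_need_rates <- function(records, mapping = frequency_mapping(),
                                use_weights = FALSE,
                                use_health_status = FALSE) {
  records <- validate_survey(records, use_weights = use_weights)
  records <- assign_stratum(records, use_health_status = use_health_status)
  records$.visits <- visits_for_record(records$visited_12m,
                                       records$frequency_category, mapping)
  records$.w <- if (use_weights) records$weight else rep(1, nrow(records))
  key <- c("sex", "age_band", if (use_health_status) "health_status")

  rates <- records |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key))) |>
    dplyr::summarise(
      n_respondents = dplyr::n(),
      effective_n = sum(.data$.w)^2 / sum(.data$.w^2),
      rate_total = sum(.data$.w * .data$.visits) / sum(.data$.w),
      .w_checkup = sum(.data$.w[.data$visited_12m &
                                  .data$last_visit_type == VISIT_TYPES[1]]),
      .w_routine = sum(.data$.w[.data$visited_12m &
                                  .data$last_visit_type == VISIT_TYPES[2]]),
      .w_emergency = sum(.data$.w[.data$visited_12m &
                                    .data$last_visit_type == VISIT_TYPES[3]]),
      .groups = "drop")
  wv <- rates$.w_checkup + rates$.w_routine + rates$.w_emergency
  share <- function(w) ifelse(wv > 0, w / wv, 0)
  rates$rate_checkup <- rates$rate_total * share(rates$.w_checkup)
  rates$rate_routine <- rates$rate_total * share(rates$.w_routine)
  rates$rate_emergency <- rates$rate_total * share(rates$.w_emergency)
  rates$.w_checkup <- rates$.w_routine <- rates$.w_emergency <- NULL

  if (!use_health_status) {
    # keep the full eight-stratum grid; empty strata are flagged, not zeroed
    grid <- tidyr::expand_grid(sex = factor(SEX_LEVELS, SEX_LEVELS),
                               age_band = factor(AGE_BAND_LEVELS,
                                                 AGE_BAND_LEVELS))
    rates <- dplyr::left_join(grid, rates, by = c("sex", "age_band"))
    rates$n_respondents[is.na(rates$n_respondents)] <- 0L
  }
  rates$defined <- rates$n_respondents > 0
  if (any(!rates$defined)) {
    log_info("%d stratum/strata with no respondents: rates undefined",
             sum(!rates$defined))
  }
  rates <- dplyr::relocate(rates, "rate_total",
                           .after = "rate_emergency")
  attr(rates, "mapping") <- mapping
  attr(rates, "weighted") <- use_weights
  class(rates) <- c("need_rates", class(rates))
  rates
}

#' Bootstrap percentile intervals for stratum visit rates
#'
#' Resamples whole respondent records with replacement within each stratum
#' (stratified nonparametric bootstrap), re-estimates the per-capita rates on
#' each resample, and returns percentile intervals. Reproducible for a fixed
#' seed.
#'
#' @inheritParams estimate_need_rates
#' @param B Number of bootstrap resamples (>= 1).
#' @param seed Integer seed.
#' @param level Interval coverage level, default 0.95.
#' @return A tibble with one row per stratum x measure (`rate_total`,
#'   `rate_checkup`, `rate_routine`, `rate_emergency`): point estimate from
#'   the full sample plus percentile `lower` and `upper`.
#' @export
bootstrap_need_rates <- function(records, mapping = frequency_mapping(),
                                 B, seed, use_weights = FALSE,
                                 use_health_status = FALSE, level = 0.95) {
  check_scalar(B, "B", lower = 1, integerish = TRUE)
  records <- validate_survey(records, use_weights = use_weights)
  records <- assign_stratum(records, use_health_status = use_health_status)
  visits <- visits_for_record(records$visited_12m,
                              records$frequency_category, mapping)
  w <- if (use_weights) records$weight else rep(1, nrow(records))
  type_idx <- match(as.character(records$last_visit_type), VISIT_TYPES)
  type_idx[!records$visited_12m] <- NA_integer_
  key <- if (use_health_status) {
    interaction(records$sex, records$age_band, records$health_status,
                drop = TRUE, lex.order = TRUE, sep = " / ")
  } else {
    interaction(records$sex, records$age_band, drop = TRUE, lex.order = TRUE,
                sep = " / ")
  }
  idx_by_stratum <- split(seq_len(nrow(records)), key)

  rate_one <- function(ii) {
    wv <- w[ii]
    total <- sum(wv * visits[ii]) / sum(wv)
    vis <- ii[records$visited_12m[ii]]
    tw <- vapply(1:3, function(k) sum(w[vis][type_idx[vis] == k]), numeric(1))
    shares <- if (sum(tw) > 0) tw / sum(tw) else c(0, 0, 0)
    c(total, total * shares)
  }

  point <- t(vapply(idx_by_stratum, rate_one, numeric(4)))
  draws <- array(NA_real_, dim = c(B, length(idx_by_stratum), 4))
  with_seed(seed, {
    for (b in seq_len(B)) {
      for (s in seq_along(idx_by_stratum)) {
        ii <- idx_by_stratum[[s]]
        draws[b, s, ] <- rate_one(ii[sample.int(length(ii), length(ii),
                                                replace = TRUE)])
      }
    }
  })
  alpha <- (1 - level) / 2
  measures <- c("rate_total", "rate_checkup", "rate_routine", "rate_emergency")
  out <- purrr::map_dfr(seq_along(idx_by_stratum), function(s) {
    tibble::tibble(
      stratum = names(idx_by_stratum)[s],
      measure = measures,
      estimate = point[s, ],
      lower = vapply(1:4, function(m)
        unname(quantile(draws[, s, m], alpha)), numeric(1)),
      upper = vapply(1:4, function(m)
        unname(quantile(draws[, s, m], 1 - alpha)), numeric(1)))
  })
  attr(out, "B") <- B
  attr(out, "seed") <- seed
  attr(out, "level") <- level
  out
}
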