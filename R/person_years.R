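# Person-year (Lexis) expansion and standardised mortality ratios.
#
# Follow-up starts at office entry — never at birth or at an earlier
# election — which is what protects the comparison from immortal time bias:
# a politician cannot die before being elected, so any person-time before
# entry would be artificially death-free. Follow-up is cut at every Jan 1
# and every birthday so each slice sits inside a single (calendar year x
# age) Lexis cell, and ends at death, at the last life-table year, or at an
# optional follow-up horizon. Exposure is measured in days / 365.25;
# the death day itself is not counted as exposure.

followup_bounds <- function(records, last_year, max_followup_years = NULL) {
  start <- records$office_date
  cap <- jan1(last_year + 1L)
  if (!is.null(max_followup_years)) {
    cap <- pmin(cap, add_years(records$office_date, max_followup_years))
  } else {
    cap <- rep(cap, nrow(records))
  }
  death <- records$death_date
  died <- !is.na(death) & death < cap
  end <- cap
  end[died] <- death[died]
  list(start = start, end = end, died = died)
}

#' Expand cohort follow-up into person-year slices
#'
#' Splits every person's follow-up into slices, each contained in one
#' (calendar year x integer age) Lexis cell. Slices begin at the office
#' date (entry into the cohort), are cut at every Jan 1 and every birthday,
#' and end at the earliest of the death date, Dec 31 of `last_year`, and
#' `office_date + max_followup_years`. A person elected halfway through a
#' calendar year therefore contributes half a year of exposure to that
#' year — expected deaths are pro-rated automatically.
#'
#' @param records retained cohort data.table (see [apply_exclusions()]).
#' @param surface an annual [lifetable_surface()] (used only for its year
#'   range when `last_year` is missing).
#' @param last_year last calendar year with life-table data; deaths after it
#'   are censored at Dec 31 of that year.
#' @param max_followup_years optional follow-up horizon in years; deaths at
#'   or beyond the horizon anniversary are censored.
#' @return data.table with columns `id, country, sex, calendar_year, age,
#'   exposure_days, exposure, died_in_slice`.
#' @export
expand_person_years <- function(records, surface = NULL, last_year = NULL,
                                max_followup_years = NULL) {
  rec <- data.table::as.data.table(records)
  if (is.null(last_year)) {
    if (is.null(surface)) stop("supply `surface` or `last_year`")
    last_year <- max(surface_years(surface))
  }
  fb <- followup_bounds(rec, last_year, max_followup_years)
  keep <- fb$start < fb$end
  if (!all(keep)) {
    warning(sum(!keep), " record(s) have no follow-up within the ",
            "life-table span and contribute no person-time")
  }
  rec <- rec[keep]
  if (nrow(rec) == 0) {
    return(data.table::data.table(
      id = character(0), country = character(0), sex = character(0),
      calendar_year = integer(0), age = integer(0),
      exposure_days = numeric(0), exposure = numeric(0),
      died_in_slice = logical(0)))
  }
  start <- fb$start[keep]; end <- fb$end[keep]; died <- fb$died[keep]
  y_first <- year_of(start)
  y_last <- year_of(end - 1L)
  nyr <- y_last - y_first + 1L
  idx <- rep(seq_len(nrow(rec)), nyr)
  yr <- y_first[idx] + (sequence(nyr) - 1L)
  cs <- pmax(start[idx], jan1(yr))
  ce <- pmin(end[idx], jan1(yr + 1L))
  bday <- anniversary(rec$birth_date[idx], yr)
  mid <- pmin(pmax(bday, cs), ce)
  build <- function(s, e) {
    len <- as.numeric(e - s)
    ok <- len > 0
    data.table::data.table(
      id = rec$id[idx][ok], country = rec$country[idx][ok],
      sex = rec$sex[idx][ok], calendar_year = yr[ok],
      age = age_at(s[ok], rec$birth_date[idx][ok]),
      exposure_days = len[ok], exposure = len[ok] / DAYS_PER_YEAR,
      died_in_slice = (died[idx] & e == end[idx])[ok]
    )
  }
  slices <- data.table::rbindlist(list(build(cs, mid), build(mid, ce)))
  data.table::setkeyv(slices, c("id", "calendar_year", "age"))
  slices[]
}

#' Expected deaths by calendar year from life-table matching
#'
#' Each slice contributes `exposure * mu` where `mu = -log(1 - qx)` is the
#' constant within-cell hazard implied by the matched life-table death
#' probability. This convention makes expected deaths exactly proportional
#' to partial-year exposure (the pro-rata adjustment for election part-way
#' through a year) and additive over any further slice cuts.
#'
#' @param slices output of [expand_person_years()].
#' @param surface an annual [lifetable_surface()].
#' @return data.table with `country, calendar_year, expected`.
#' @export
expected_deaths <- function(slices, surface) {
  mu <- qx_to_mu(qx_lookup(surface, slices$sex, slices$calendar_year,
                           slices$age))
  contrib <- slices$exposure * mu
  out <- data.table::data.table(country = slices$country,
                                calendar_year = slices$calendar_year,
                                contrib = contrib)
  out <- out[, list(expected = sum(contrib)),
             by = c("country", "calendar_year")]
  data.table::setkeyv(out, c("country", "calendar_year"))
  out[]
}

#' Yearly standardised mortality ratios
#'
#' Observed deaths are deaths whose date falls in the year and inside
#' follow-up; expected deaths come from [expected_deaths()]. SMR =
#' observed / expected, undefined (NA) where expected is zero.
#'
#' @inheritParams expand_person_years
#' @return data.table with `country, calendar_year, observed, expected,
#'   smr` covering every year from cohort start to `last_year`.
#' @export
smr_by_year <- function(records, surface, last_year = NULL,
                        max_followup_years = NULL) {
  rec <- data.table::as.data.table(records)
  if (is.null(last_year)) last_year <- max(surface_years(surface))
  slices <- expand_person_years(rec, surface, last_year, max_followup_years)
  if (nrow(slices) == 0) stop("no person-time in the cohort")
  exp_dt <- expected_deaths(slices, surface)
  fb <- followup_bounds(rec, last_year, max_followup_years)
  obs_year <- year_of(rec$death_date[fb$died])
  obs_country <- rec$country[fb$died]
  grid <- data.table::data.table(
    country = rep(sort(unique(rec$country)),
                  each = last_year - min(slices$calendar_year) + 1L),
    calendar_year = seq(min(slices$calendar_year), last_year)
  )
  obs_dt <- data.table::data.table(country = obs_country,
                                   calendar_year = obs_year, n = 1L)
  obs_dt <- obs_dt[, list(observed = sum(n)),
                   by = c("country", "calendar_year")]
  out <- merge(grid, obs_dt, by = c("country", "calendar_year"), all.x = TRUE)
  out <- merge(out, exp_dt, by = c("country", "calendar_year"), all.x = TRUE)
  out$observed[is.na(out$observed)] <- 0L
  out$expected[is.na(out$expected)] <- 0
  out$smr <- ifelse(out$expected > 0, out$observed / out$expected, NA_real_)
  out[]
}

#' Pooled SMR over all years
#' @param yearly output of [smr_by_year()].
#' @return total observed / total expected.
#' @export
pooled_smr <- function(yearly) sum(yearly$observed) / sum(yearly$expected)

#' SMR sensitivity to the follow-up horizon
#'
#' Re-runs the SMR computation while censoring follow-up at a ladder of
#' horizons (deaths beyond the horizon are not counted and people are
#' censored there). Passive tracking of deaths makes long follow-up
#' vulnerable to unknown loss to follow-up; short horizons reduce both the
#' propensity and the impact of such loss, so comparing horizons is a
#' robustness check on the SMR trend.
#'
#' @inheritParams expand_person_years
#' @param horizons integer vector of follow-up horizons in years.
#' @return long data.table: `horizon, country, calendar_year, observed,
#'   expected, smr`.
#' @export
followup_sensitivity <- function(records, surface, horizons = seq(10, 60, 10),
                                 last_year = NULL) {
  out <- lapply(horizons, function(h) {
    cbind(horizon = h,
          smr_by_year(records, surface, last_year, max_followup_years = h))
  })
  data.table::rbindlist(out)
}

#' Directly standardized mortality-rate ratio for one year
#'
#' Compares the cohort's age-standardized death rate with the population's,
#' both weighted by the same standard-population age bands, restricted to
#' bands where the cohort has person-time (bands with zero cohort exposure
#' contribute zero to both sides and are reported). The population band
#' rate mixes male and female hazards with the cohort's person-year sex
#' split in that band. The CI uses the usual log-normal approximation for a
#' standardized rate, treating population rates as known.
#'
#' @param records retained cohort data.table.
#' @param surface an annual [lifetable_surface()].
#' @param weights standard-population weights from [read_standard_weights()].
#' @param year calendar year to standardize.
#' @param last_year passed through to the person-year expansion.
#' @return one-row data.table: `calendar_year, ratio, lo95, hi95,
#'   asr_cohort, asr_population, empty_bands`.
#' @export
direct_standardized_ratio <- function(records, surface, weights, year,
                                      last_year = NULL) {
  slices <- expand_person_years(records, surface, last_year)
  sl <- slices[slices$calendar_year == year]
  if (nrow(sl) == 0) stop("no cohort person-time in year ", year)
  band <- findInterval(sl$age, weights$age_lo)
  mu <- qx_to_mu(qx_lookup(surface, sl$sex, sl$calendar_year, sl$age))
  agg <- data.table::data.table(
    band = band, exposure = sl$exposure,
    death = as.numeric(sl$died_in_slice),
    pop = sl$exposure * mu
  )
  agg <- agg[, list(py = sum(exposure), deaths = sum(death),
                    pop_expected = sum(pop)), by = "band"]
  out <- standardized_ratio_core(agg, weights)
  cbind(calendar_year = year, out)
}

# band-level core: cohort rate = deaths/py, population rate =
# pop_expected/py, both weighted by the standard population over bands with
# cohort person-time
standardized_ratio_core <- function(band_table, weights) {
  full <- merge(data.table::data.table(band = seq_len(nrow(weights)),
                                       weight = weights$weight),
                band_table, by = "band", all.x = TRUE)
  empty <- is.na(full$py) | full$py <= 0
  full$py[empty] <- 0; full$deaths[empty] <- 0; full$pop_expected[empty] <- 0
  used <- !empty
  r_cohort <- ifelse(used, full$deaths / pmax(full$py, 1e-300), 0)
  r_pop <- ifelse(used, full$pop_expected / pmax(full$py, 1e-300), 0)
  asr_c <- sum(full$weight * r_cohort)
  asr_p <- sum(full$weight * r_pop)
  ratio <- asr_c / asr_p
  var_asr <- sum((full$weight[used])^2 * full$deaths[used] /
                   (full$py[used])^2)
  se_log <- if (asr_c > 0) sqrt(var_asr) / asr_c else NA_real_
  data.table::data.table(
    ratio = ratio,
    lo95 = ratio * exp(-1.959964 * se_log),
    hi95 = ratio * exp(1.959964 * se_log),
    asr_cohort = asr_c, asr_population = asr_p,
    empty_bands = paste(weights$age_group[empty], collapse = ";")
  )
}
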