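# Synthetic life tables and cohorts with known ground truth.
#
# Population mortality follows a Gompertz-Makeham hazard per sex,
#   mu(age, year) = (a + b0 * exp(g * (age - 45))) * exp(-improvement * (year - start)),
# i.e. an age pattern realistic for adult mortality combined with a steady
# proportional secular decline. The elite cohort's hazard is a specified
# calendar-time-varying multiple (hazard ratio curve) of the population
# hazard, so the true SMR curve and true life-expectancy gaps are known by
# construction. Death times are drawn by inversion of the piecewise-constant
# per-Lexis-cell cumulative hazard — exactly the convention the SMR engine
# uses — so simulator and estimator share one discretization.

#' Hazard-ratio curve constructors
#'
#' Shapes for the cohort-vs-population hazard ratio as a function of
#' calendar year: constant, linear, or a logistic decline (high early, low
#' late — the elite survival advantage emerging over the twentieth
#' century).
#'
#' @param value,from,to,midpoint,rate curve parameters.
#' @return a list describing the curve, usable in [synthetic_scenario()].
#' @export
hr_constant <- function(value = 1) list(kind = "constant", value = value)

#' @rdname hr_constant
#' @export
hr_linear <- function(from = 1, to = 0.6) {
  list(kind = "linear", from = from, to = to)
}

#' @rdname hr_constant
#' @export
hr_logistic <- function(from = 1, to = 0.55, midpoint = 1950, rate = 0.08) {
  list(kind = "logistic", from = from, to = to, midpoint = midpoint,
       rate = rate)
}

hr_at <- function(scenario, year) {
  cv <- scenario$hr_curve
  y0 <- scenario$years[1]; y1 <- scenario$years[2]
  switch(cv$kind,
    constant = rep(cv$value, length(year)),
    linear = cv$from + (cv$to - cv$from) * (year - y0) / (y1 - y0),
    logistic = cv$to + (cv$from - cv$to) /
      (1 + exp(cv$rate * (year - cv$midpoint))),
    stop("unknown hr curve kind: ", cv$kind)
  )
}

female_fraction_at <- function(scenario, year) {
  fs <- scenario$female_start; fe <- scenario$years[2]
  frac <- ifelse(year < fs, 0,
                 scenario$female_end_fraction * (year - fs) / (fe - fs))
  pmin(pmax(frac, 0), 1)
}

#' Define a synthetic study scenario
#'
#' Defaults emulate the conditions of a long-run politician-mortality
#' study: a 1850-2015 span, Gompertz-Makeham population mortality with a
#' 1% annual proportional hazard decline, entry ages centred near 45, no
#' women before 1920 with a linear rise afterwards, life tables emitted
#' only every 5 years (exercising interpolation, as early historical
#' tables demand), and an elite hazard ratio declining logistically from
#' about 1 to 0.55 over the twentieth century.
#'
#' @param years span `c(first, last)` of calendar years.
#' @param makeham per-sex Gompertz-Makeham parameters: lists with `a`
#'   (background hazard), `b0` (hazard at age 45 in the first year), `g`
#'   (log-hazard slope per year of age).
#' @param improvement annual proportional hazard decline per calendar year.
#' @param hr_curve cohort hazard-ratio curve ([hr_constant()],
#'   [hr_linear()] or [hr_logistic()]).
#' @param n_politicians cohort size.
#' @param entry_age_mean,entry_age_sd entry-age distribution (Normal,
#'   truncated to 25-75).
#' @param female_start first year with any female entries.
#' @param female_end_fraction female fraction reached in the last year.
#' @param table_spacing years between emitted life tables (1, 5 or 10).
#' @param omega terminal life-table age.
#' @param country label for generated data.
#' @param seed RNG seed; every generator is seed-deterministic.
#' @return object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(
    years = c(1850, 2015),
    makeham = list(
      male = list(a = 5e-4, b0 = 0.012, g = 0.085),
      female = list(a = 4e-4, b0 = 0.008, g = 0.090)
    ),
    improvement = 0.01,
    hr_curve = hr_logistic(),
    n_politicians = 10000,
    entry_age_mean = 45, entry_age_sd = 7,
    female_start = 1920, female_end_fraction = 0.2,
    table_spacing = 5,
    omega = 110,
    country = "Synthetia",
    seed = 2026) {
  stopifnot(years[2] > years[1],
            (years[2] - years[1]) %% table_spacing == 0,
            female_end_fraction >= 0, female_end_fraction <= 1,
            improvement >= 0)
  for (s in c("male", "female")) {
    stopifnot(makeham[[s]]$a >= 0, makeham[[s]]$b0 > 0)
  }
  structure(list(
    years = years, makeham = makeham, improvement = improvement,
    hr_curve = hr_curve, n_politicians = n_politicians,
    entry_age_mean = entry_age_mean, entry_age_sd = entry_age_sd,
    female_start = female_start, female_end_fraction = female_end_fraction,
    table_spacing = table_spacing, omega = omega, country = country,
    seed = seed
  ), class = "synthetic_scenario")
}

# generating hazard, vectorized over age/year
mu_true <- function(scenario, age, year, sex) {
  n <- max(length(age), length(year), length(sex))
  age <- rep_len(age, n); year <- rep_len(year, n); sex <- rep_len(sex, n)
  out <- numeric(n)
  for (s in c("male", "female")) {
    i <- sex == s
    if (!any(i)) next
    p <- scenario$makeham[[s]]
    out[i] <- (p$a + p$b0 * exp(p$g * (age[i] - 45))) *
      exp(-scenario$improvement * (year[i] - scenario$years[1]))
  }
  out
}

# exact cumulative hazard over the one-year age interval [age, age+1) at
# fixed calendar year, so that qx = 1 - exp(-integral) is consistent with
# the continuous generating hazard (a point-evaluated hazard would bias
# e(45) upward by ~0.4 years at g ~ 0.085)
mu_cell_true <- function(scenario, age, year, sex) {
  n <- max(length(age), length(year), length(sex))
  age <- rep_len(age, n); year <- rep_len(year, n); sex <- rep_len(sex, n)
  out <- numeric(n)
  for (s in c("male", "female")) {
    i <- sex == s
    if (!any(i)) next
    p <- scenario$makeham[[s]]
    out[i] <- (p$a + p$b0 * (gomp_E(age[i] + 1 - 45, p$g) -
                               gomp_E(age[i] - 45, p$g))) *
      exp(-scenario$improvement * (year[i] - scenario$years[1]))
  }
  out
}

#' True remaining life expectancy under the generating hazard
#'
#' Period remaining life expectancy at `age` in calendar year `year`,
#' computed from the continuous generating hazard (optionally multiplied
#' by a constant hazard ratio) by adaptive quadrature. Serves as the
#' ground-truth oracle against which life-table and Gompertz estimates are
#' compared.
#'
#' @param scenario a [synthetic_scenario()].
#' @param sex "male" or "female".
#' @param year calendar year.
#' @param age exact age (default 45).
#' @param hr constant hazard multiplier (default 1 = general population).
#' @return years.
#' @export
true_remaining_le <- function(scenario, sex, year, age = 45, hr = 1) {
  p <- scenario$makeham[[sex]]
  scale <- hr * exp(-scenario$improvement * (year - scenario$years[1]))
  t0 <- age - 45
  S <- function(u) {
    exp(-scale * (p$a * u + p$b0 * (gomp_E(t0 + u, p$g) - gomp_E(t0, p$g))))
  }
  stats::integrate(S, 0, 130 - age, rel.tol = 1e-10,
                   subdivisions = 1000L)$value
}

#' Generate a synthetic life-table surface
#'
#' Emits `qx = 1 - exp(-mu)` from the generating hazard at
#' `table_spacing`-year intervals (exercising the interpolation stage when
#' spacing > 1). The manifest records the generating parameters and true
#' continuous remaining life expectancies at 45 for every emitted
#' (sex, year).
#'
#' @param scenario a [synthetic_scenario()].
#' @param spacing overrides the scenario's `table_spacing` (use 1 for the
#'   exact annual surface).
#' @return list with `surface` (a [lifetable_surface()]) and `manifest`
#'   (generating parameters plus a data.table of true e(45) values).
#' @export
make_surface <- function(scenario, spacing = scenario$table_spacing) {
  years <- seq(scenario$years[1], scenario$years[2], by = spacing)
  ages <- 0:scenario$omega
  grid <- data.table::CJ(sex = c("male", "female"), year = years, age = ages)
  grid$qx <- mu_to_qx(mu_cell_true(scenario, grid$age, grid$year, grid$sex))
  surface <- lifetable_surface(grid, country = scenario$country)
  e45 <- data.table::CJ(sex = c("male", "female"), year = years)
  e45$e45_true <- mapply(function(s, y) true_remaining_le(scenario, s, y),
                         e45$sex, e45$year)
  manifest <- list(
    scenario = scenario, emitted_years = years,
    true_e45 = e45
  )
  list(surface = surface, manifest = manifest)
}

#' Simulate an elite cohort with known hazard ratio
#'
#' Entry dates are uniform over the span; sex follows the scenario's
#' female-fraction curve; entry ages are truncated-Normal around 45. Death
#' times are drawn by exact inversion of the piecewise-constant
#' per-Lexis-cell cumulative hazard `hr(year) * mu(age, year, sex)`, using
#' the same annual `qx`-derived cell hazards the SMR engine matches
#' against; follow-up is censored at the end of the span. The manifest
#' records the true SMR for every calendar year (the hazard-ratio curve).
#'
#' @param scenario a [synthetic_scenario()].
#' @return list with `records` (cohort data.table), `manifest` (true SMR
#'   by year plus the scenario) and `surface_annual` (the exact annual
#'   [lifetable_surface()] used for simulation).
#' @export
simulate_cohort <- function(scenario) {
  annual <- make_surface(scenario, spacing = 1)$surface
  set.seed(scenario$seed)
  n <- scenario$n_politicians
  y0 <- scenario$years[1]; y1 <- scenario$years[2]
  span_days <- as.integer(jan1(y1 + 1L) - jan1(y0))
  entry <- jan1(y0) + sample.int(span_days, n, replace = TRUE) - 1L
  entry_age <- stats::rnorm(n, scenario$entry_age_mean, scenario$entry_age_sd)
  while (any(bad <- entry_age < 25 | entry_age > 75)) {
    entry_age[bad] <- stats::rnorm(sum(bad), scenario$entry_age_mean,
                                   scenario$entry_age_sd)
  }
  birth <- entry - as.integer(round(entry_age * DAYS_PER_YEAR))
  p_f <- female_fraction_at(scenario, year_of(entry))
  sex <- ifelse(stats::runif(n) < p_f, "female", "male")
  hr_year <- hr_at(scenario, y0:y1)

  cap <- jan1(y1 + 1L)
  cur <- entry
  E <- stats::rexp(n)
  death <- as.Date(rep(NA, n))
  active <- rep(TRUE, n)
  while (any(active)) {
    i <- which(active)
    yr <- year_of(cur[i])
    b_this <- anniversary(birth[i], yr)
    b_next <- anniversary(birth[i], yr + 1L)
    next_bday <- data.table::fifelse(b_this > cur[i], b_this, b_next)
    nxt <- pmin(next_bday, jan1(yr + 1L), cap)
    dt_years <- as.numeric(nxt - cur[i]) / DAYS_PER_YEAR
    age <- age_at(cur[i], birth[i])
    lambda <- hr_year[yr - y0 + 1L] *
      qx_to_mu(qx_lookup(annual, sex[i], yr, age))
    h_cell <- lambda * dt_years
    dies <- E[i] <= h_cell
    if (any(dies)) {
      j <- i[dies]
      dd <- cur[j] + floor((E[j] / lambda[dies]) * DAYS_PER_YEAR)
      death[j] <- pmin(dd, nxt[dies] - 1L)
      active[j] <- FALSE
    }
    stay <- !dies
    E[i[stay]] <- E[i[stay]] - h_cell[stay]
    cur[i[stay]] <- nxt[stay]
    active[active & cur >= cap] <- FALSE
  }
  records <- data.table::data.table(
    id = sprintf("P%06d", seq_len(n)),
    country = scenario$country, sex = sex,
    birth_date = birth, death_date = death, office_date = entry,
    status = ifelse(is.na(death), "alive", "dead")
  )
  manifest <- list(
    scenario = scenario,
    true_smr = data.table::data.table(calendar_year = y0:y1,
                                      smr_true = hr_year)
  )
  list(records = records, manifest = manifest, surface_annual = annual)
}

#' True life-expectancy gap in a calendar window
#'
#' Ground truth for the window gap estimator: the mean over window years of
#' the continuous period remaining life expectancy at `age` under the
#' cohort hazard (`hr(year) * mu`), minus the same under the population
#' hazard, both mixed with the supplied male fraction.
#'
#' @param scenario a [synthetic_scenario()].
#' @param window `c(start, end)` inclusive calendar years.
#' @param male_fraction sex mix for pooling.
#' @param age reference age (default 45).
#' @return list with `le_cohort`, `le_population`, `gap` (years).
#' @export
true_le_gap <- function(scenario, window, male_fraction, age = 45) {
  years <- seq(window[1], window[2])
  hrw <- hr_at(scenario, years)
  mix <- function(hr_vals) {
    mean(vapply(seq_along(years), function(k) {
      male_fraction *
        true_remaining_le(scenario, "male", years[k], age, hr_vals[k]) +
        (1 - male_fraction) *
        true_remaining_le(scenario, "female", years[k], age, hr_vals[k])
    }, numeric(1)))
  }
  le_c <- mix(hrw)
  le_p <- mix(rep(1, length(years)))
  list(le_cohort = le_c, le_population = le_p, gap = le_c - le_p)
}

#' Plant data defects for testing the exclusion rules
#'
#' Corrupts a clean cohort at stated rates: deletes birth dates, marks
#' people dead with an unknown death date, shifts office dates before the
#' first life-table year, and plants under-21 entries. Defects are applied
#' to disjoint record subsets; the manifest counts each defect.
#'
#' @param records cohort data.table.
#' @param rates named list of rates in \[0, 1\]: `missing_birth`,
#'   `dead_missing_death`, `office_before_tables`, `under_21`.
#' @param first_table_year used to shift office dates out of range.
#' @param seed RNG seed.
#' @return list with `records` (corrupted copy) and `manifest` (counts per
#'   defect).
#' @export
planted_defects <- function(records,
                            rates = list(missing_birth = 0.05,
                                         dead_missing_death = 0,
                                         office_before_tables = 0,
                                         under_21 = 0),
                            first_table_year, seed = 1) {
  rec <- data.table::copy(data.table::as.data.table(records))
  set.seed(seed)
  n <- nrow(rec)
  pool <- sample.int(n)  # random order; defects drawn disjointly
  take <- function(k) {
    k <- min(k, length(pool))
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  counts <- list()
  i <- take(round((rates$missing_birth %||% 0) * n))
  rec$birth_date[i] <- as.Date(NA)
  counts$missing_birth <- length(i)
  i <- take(round((rates$dead_missing_death %||% 0) * n))
  rec$death_date[i] <- as.Date(NA)
  rec$status[i] <- "dead"
  counts$dead_missing_death <- length(i)
  i <- take(round((rates$office_before_tables %||% 0) * n))
  rec$office_date[i] <- jan1(first_table_year - 5L) +
    sample.int(365L, length(i), replace = TRUE) - 1L
  counts$office_before_tables <- length(i)
  i <- take(round((rates$under_21 %||% 0) * n))
  rec$office_date[i] <- add_years(rec$birth_date[i], 19L)
  counts$under_21 <- length(i)
  list(records = rec, manifest = counts)
}
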