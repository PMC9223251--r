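# Independent oracles used across test files. These deliberately avoid the
# package's internal date helpers and slice engine: ages come from string
# month-day comparison, exposure from day-by-day accumulation, integrals
# from fixed-grid trapezoids.

# Day-by-day brute-force exposure and expected deaths for one record.
# Returns per (calendar_year, age) day counts and expected deaths.
day_oracle <- function(rec, surface, last_year, max_followup_years = NULL) {
  office <- rec$office_date
  cap <- as.Date(sprintf("%04d-01-01", last_year + 1L))
  if (!is.null(max_followup_years)) {
    y <- as.integer(format(office, "%Y")) + max_followup_years
    md <- format(office, "%m-%d")
    ann <- suppressWarnings(as.Date(paste0(y, "-", md)))
    if (is.na(ann)) ann <- as.Date(paste0(y, "-03-01"))
    cap <- min(cap, ann)
  }
  end <- cap
  died <- FALSE
  if (!is.na(rec$death_date) && rec$death_date < cap) {
    end <- rec$death_date
    died <- TRUE
  }
  if (end <= office) {
    return(list(cells = data.frame(), expected_by_year = numeric(0),
                died = FALSE, death_year = NA_integer_))
  }
  days <- seq(office, end - 1, by = "day")
  yr <- as.integer(format(days, "%Y"))
  md <- format(days, "%m-%d")
  b_md <- format(rec$birth_date, "%m-%d")
  age <- yr - as.integer(format(rec$birth_date, "%Y")) - (md < b_md)
  cells <- aggregate(list(n_days = rep(1L, length(days))),
                     by = list(calendar_year = yr, age = age), FUN = sum)
  mu <- -log(1 - pmin(qx_lookup(surface, rec$sex, cells$calendar_year,
                                cells$age), 1 - 1e-10))
  cells$expected <- cells$n_days / 365.25 * mu
  eby <- tapply(cells$expected, cells$calendar_year, sum)
  list(cells = cells, expected_by_year = eby, died = died,
       death_year = if (died) as.integer(format(end, "%Y")) else NA_integer_)
}

# Fine-grid trapezoid remaining-life-expectancy oracle for a Gompertz
# hazard h(u) = B exp(g u) from the reference age.
gompertz_le_trapezoid <- function(B, g, du = 5e-4) {
  upper <- if (abs(g) < 1e-10) -log(1e-13) / B
           else log1p(g * (-log(1e-13)) / B) / g
  u <- seq(0, upper, by = du)
  H <- if (abs(g) < 1e-10) B * u else (B / g) * expm1(g * u)
  S <- exp(-H)
  du * (sum(S) - (S[1] + S[length(S)]) / 2)
}

# small hand-built surface: constant qx by age for a run of years
flat_surface <- function(qx_male = 0.02, qx_female = 0.015,
                         years = 1990:2000, omega = 110,
                         country = "Testland") {
  grid <- expand.grid(sex = c("male", "female"), year = years,
                      age = 0:omega, stringsAsFactors = FALSE)
  grid$qx <- ifelse(grid$sex == "male", qx_male, qx_female)
  lifetable_surface(grid, country = country)
}

# minimal valid cohort table
toy_records <- function(n = 3, year = 1995) {
  data.table::data.table(
    id = sprintf("T%02d", seq_len(n)),
    country = "Testland",
    sex = rep("male", n),
    birth_date = as.Date(sprintf("%d-06-15", year - 50 - seq_len(n))),
    death_date = as.Date(NA),
    office_date = as.Date(sprintf("%d-03-01", year - seq_len(n))),
    status = "alive"
  )
}
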