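# Person-year expansion, expected deaths, SMR.

test_that("election halfway through a (leap) year halves first-year exposure", {
  surf <- flat_surface(qx_male = 0.02, years = 1950:1960)
  # 1952 is a leap year: Jan 1 + 183 days = Jul 2, exactly half of 366 days
  rec <- data.table::data.table(
    id = "half", country = "Testland", sex = "male",
    birth_date = as.Date("1900-01-01"), death_date = as.Date(NA),
    office_date = as.Date("1952-01-01") + 183L, status = "alive"
  )
  full <- data.table::copy(rec)
  full$office_date <- as.Date("1952-01-01")
  sl_half <- expand_person_years(rec, surf, last_year = 1960)
  sl_full <- expand_person_years(full, surf, last_year = 1960)
  e_half <- sum(sl_half$exposure[sl_half$calendar_year == 1952])
  e_full <- sum(sl_full$exposure[sl_full$calendar_year == 1952])
  expect_identical(e_half * 2, e_full)
  # and the expected deaths are exactly halved too (pro-rata contract)
  x_half <- expected_deaths(sl_half[sl_half$calendar_year == 1952], surf)
  x_full <- expected_deaths(sl_full[sl_full$calendar_year == 1952], surf)
  expect_equal(x_half$expected * 2, x_full$expected, tolerance = 1e-12)
})

test_that("death the day after taking office leaves one ~1/365-year slice", {
  surf <- flat_surface(years = 1950:1960)
  rec <- data.table::data.table(
    id = "x", country = "Testland", sex = "male",
    birth_date = as.Date("1900-06-15"),
    death_date = as.Date("1955-03-02"),
    office_date = as.Date("1955-03-01"), status = "dead"
  )
  sl <- expand_person_years(rec, surf, last_year = 1960)
  expect_equal(nrow(sl), 1)
  expect_equal(sl$exposure_days, 1)
  expect_true(sl$died_in_slice)
})

test_that("slices tile follow-up exactly and die at most once, in the last slice", {
  sc <- synthetic_scenario(years = c(1950, 2000), table_spacing = 1,
                           n_politicians = 300, seed = 14)
  sim <- simulate_cohort(sc)
  surf <- sim$surface_annual
  sl <- expand_person_years(sim$records, surf)
  fb <- elitemort:::followup_bounds(sim$records, 2000)
  tot <- sl[, list(days = sum(exposure_days),
                   deaths = sum(died_in_slice)), by = "id"]
  m <- merge(tot,
             data.table::data.table(id = sim$records$id,
                                    span = as.numeric(fb$end - fb$start),
                                    died = fb$died),
             by = "id")
  expect_equal(m$days, m$span)
  expect_equal(m$deaths, as.integer(m$died))
  # each slice sits in one Lexis cell: one (year, age) pair per slice row
  expect_true(all(sl$exposure_days <= 366))
})

test_that("slice-based expected deaths equal the day-by-day oracle", {
  sc <- synthetic_scenario(years = c(1950, 2000), table_spacing = 1,
                           n_politicians = 40, seed = 15)
  sim <- simulate_cohort(sc)
  surf <- sim$surface_annual
  sl <- expand_person_years(sim$records, surf)
  for (i in seq_len(nrow(sim$records))) {
    rec <- sim$records[i]
    oracle <- day_oracle(rec, surf, 2000)
    mine <- expected_deaths(sl[sl$id == rec$id], surf)
    if (nrow(mine) == 0 && length(oracle$expected_by_year) == 0) next
    expect_equal(mine$expected,
                 as.numeric(oracle$expected_by_year[
                   as.character(mine$calendar_year)]),
                 tolerance = 1e-10)
  }
})

test_that("single-cell expected deaths follow the hazard convention", {
  surf <- flat_surface(qx_male = 0.01, years = 1990:1999)
  sl <- data.table::data.table(
    id = "x", country = "Testland", sex = "male", calendar_year = 1995L,
    age = 50L, exposure_days = 365.25, exposure = 1,
    died_in_slice = FALSE
  )
  out <- expected_deaths(sl, surf)
  expect_equal(out$expected, -log(0.99), tolerance = 1e-12)
  sl$exposure <- 0.5
  expect_equal(expected_deaths(sl, surf)$expected, -log(0.99) / 2,
               tolerance = 1e-12)
})

test_that("expected deaths are additive over cohort partitions and duplication", {
  sc <- synthetic_scenario(years = c(1960, 2000), table_spacing = 1,
                           n_politicians = 200, seed = 16)
  sim <- simulate_cohort(sc)
  surf <- sim$surface_annual
  y_all <- smr_by_year(sim$records, surf)
  half1 <- sim$records[1:100]; half2 <- sim$records[101:200]
  e1 <- expected_deaths(expand_person_years(half1, surf), surf)
  e2 <- expected_deaths(expand_person_years(half2, surf), surf)
  both <- merge(e1, e2, by = c("country", "calendar_year"), all = TRUE)
  both[is.na(both)] <- 0
  m <- merge(y_all, both, by = c("country", "calendar_year"), all.x = TRUE)
  m[is.na(m)] <- 0
  expect_equal(m$expected, m$expected.x + m$expected.y, tolerance = 1e-9)
  # duplicating every record doubles observed and expected, leaving SMR fixed
  dup <- data.table::copy(sim$records)
  dup$id <- paste0(dup$id, "_copy")
  y_dup <- smr_by_year(rbind(sim$records, dup), surf)
  expect_equal(sum(y_dup$observed), 2 * sum(y_all$observed))
  expect_equal(sum(y_dup$expected), 2 * sum(y_all$expected), tolerance = 1e-9)
  expect_equal(pooled_smr(y_dup), pooled_smr(y_all), tolerance = 1e-12)
})

test_that("years with no deaths get SMR zero and empty years are flagged NA", {
  surf <- flat_surface(qx_male = 0.001, years = 1990:1999)
  rec <- toy_records()
  y <- smr_by_year(rec, surf, last_year = 1999)
  expect_true(all(y$observed == 0))
  expect_true(all(y$smr[y$expected > 0] == 0))
  expect_true(all(is.na(y$smr[y$expected == 0])))
})

test_that("a horizon longer than any follow-up reproduces the unrestricted SMR", {
  sc <- synthetic_scenario(years = c(1970, 2000), table_spacing = 1,
                           n_politicians = 300, seed = 17)
  sim <- simulate_cohort(sc)
  y_free <- smr_by_year(sim$records, sim$surface_annual)
  y_cap <- smr_by_year(sim$records, sim$surface_annual,
                       max_followup_years = 80)
  expect_equal(y_free, y_cap)
})

test_that("direct standardization contracts hold exactly at band level", {
  w <- read_standard_weights()
  # cohort rates identical to population in every observed band -> ratio 1,
  # whatever the weights
  bands <- data.table::data.table(
    band = c(9, 10, 12, 14),  # 40s through 60s
    py = c(100, 250, 300, 80),
    pop_expected = c(0.9, 3.1, 6.0, 3.2)
  )
  bands$deaths <- bands$pop_expected
  r1 <- elitemort:::standardized_ratio_core(bands, w)
  expect_equal(r1$ratio, 1, tolerance = 1e-12)
  # halving every cohort rate halves the ratio regardless of weights
  bands$deaths <- bands$pop_expected / 2
  r2 <- elitemort:::standardized_ratio_core(bands, w)
  expect_equal(r2$ratio, 0.5, tolerance = 1e-12)
  # bands without person-time are reported
  expect_true(grepl("0-4", r2$empty_bands))
})

test_that("direct standardization tracks a simulated hazard ratio", {
  sc <- synthetic_scenario(years = c(1950, 2000), table_spacing = 1,
                           n_politicians = 20000,
                           hr_curve = hr_constant(0.6), seed = 12)
  sim <- simulate_cohort(sc)
  w <- read_standard_weights()
  r <- direct_standardized_ratio(sim$records, sim$surface_annual, w, 1995)
  expect_gt(r$hi95, 0.6 * 0.85)
  expect_lt(r$lo95, 0.6 * 1.15)
})
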