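# Gompertz window fits, remaining life expectancy, bootstrap, gaps.

# left-truncated Gompertz sampler used as simulation truth
sim_gompertz <- function(n, b = 0.01, g = 0.09, seed = 1,
                         entry_mean = 45, entry_sd = 3,
                         cens_lo = 5, cens_hi = 40) {
  set.seed(seed)
  entry <- pmax(stats::rnorm(n, entry_mean, entry_sd), 30)
  u <- entry - 45
  v <- log1p(g * (stats::rexp(n) / b + expm1(g * u) / g)) / g
  death_age <- 45 + v
  cens_age <- entry + stats::runif(n, cens_lo, cens_hi)
  data.table::data.table(
    id = as.character(seq_len(n)), sex = "male",
    entry_age = entry, exit_age = pmin(death_age, cens_age),
    event = death_age <= cens_age
  )
}

test_that("window slicing partitions follow-up between consecutive windows", {
  sc <- synthetic_scenario(years = c(1950, 2000), table_spacing = 1,
                           n_politicians = 200, seed = 30)
  sim <- simulate_cohort(sc)
  windows <- elitemort:::default_windows(1950, 1999)
  py <- 0; events <- 0
  for (w in windows) {
    d <- window_slices(sim$records, w, last_year = 1999)
    expect_true(all(d$exit_age > d$entry_age))
    py <- py + sum(d$exit_age - d$entry_age)
    events <- events + sum(d$event)
  }
  sl <- expand_person_years(sim$records, sim$surface_annual,
                            last_year = 1999)
  expect_equal(py, sum(sl$exposure), tolerance = 1e-9)
  expect_equal(events, sum(sl$died_in_slice))
})

test_that("a record dying inside a window is an event with office-to-death ages", {
  rec <- data.table::data.table(
    id = "x", country = "T", sex = "male",
    birth_date = as.Date("1900-01-01"),
    death_date = as.Date("1958-07-01"),
    office_date = as.Date("1952-03-01"), status = "dead"
  )
  d <- window_slices(rec, c(1950, 1959), last_year = 1990)
  expect_equal(nrow(d), 1)
  expect_true(d$event)
  expect_equal(d$entry_age, as.numeric(as.Date("1952-03-01") -
                                         as.Date("1900-01-01")) / 365.25)
  expect_equal(d$exit_age, as.numeric(as.Date("1958-07-01") -
                                        as.Date("1900-01-01")) / 365.25)
})

test_that("simulated (b, g) are recovered within 2 SE with left truncation", {
  d <- sim_gompertz(5000, b = 0.01, g = 0.09, seed = 1)
  fit <- fit_gompertz(d)
  expect_true(fit$estimable)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(log(fit$b) - log(0.01)), 2 * se[1])
  expect_lt(abs(fit$g - 0.09), 2 * se[2])
})

test_that("the fit agrees with flexsurv's Gompertz on the same data", {
  skip_if_not_installed("flexsurv")
  skip_if_not_installed("survival")
  d <- sim_gompertz(2000, seed = 2)
  fit <- fit_gompertz(d)
  fs <- flexsurv::flexsurvreg(
    survival::Surv(entry_age, exit_age, event) ~ 1, data = d,
    dist = "gompertz")
  g_fs <- fs$res["shape", "est"]
  b45_fs <- fs$res["rate", "est"] * exp(45 * g_fs)
  expect_equal(fit$g, g_fs, tolerance = 1e-4)
  expect_equal(fit$b, b45_fs, tolerance = 1e-4)
})

test_that("a null sex effect is estimated near zero", {
  d <- sim_gompertz(4000, seed = 3)
  d$sex <- rep(c("male", "female"), 2000)  # label independent of survival
  fit <- fit_gompertz(d, sex_covariate = TRUE)
  se <- sqrt(diag(fit$vcov))
  expect_lt(abs(fit$beta_sex), 2 * se[3])
})

test_that("all-censored data are unestimable, not an error", {
  d <- sim_gompertz(200, seed = 4)
  d$event <- FALSE
  fit <- fit_gompertz(d)
  expect_false(fit$estimable)
  expect_match(fit$diagnostics, "too few events")
})

test_that("remaining life expectancy matches a fine-grid trapezoid oracle", {
  fit <- structure(list(b = 0.01, g = 0.1, beta_sex = NA_real_,
                        estimable = TRUE, has_sex = FALSE),
                   class = "gompertz_fit")
  expect_lt(abs(gompertz_remaining_le(fit) -
                  gompertz_le_trapezoid(0.01, 0.1)), 0.01)
  fit$g <- 0.05
  expect_lt(abs(gompertz_remaining_le(fit) -
                  gompertz_le_trapezoid(0.01, 0.05)), 0.01)
})

test_that("the g -> 0 limit reduces to the exponential lifetime 1/b", {
  fit <- structure(list(b = 0.01, g = 1e-8, beta_sex = NA_real_,
                        estimable = TRUE, has_sex = FALSE),
                   class = "gompertz_fit")
  e <- gompertz_remaining_le(fit)
  expect_lt(abs(e - 100) / 100, 0.001)
})

test_that("doubling b strictly decreases remaining life expectancy", {
  f1 <- structure(list(b = 0.01, g = 0.09, beta_sex = NA_real_,
                       estimable = TRUE, has_sex = FALSE),
                  class = "gompertz_fit")
  f2 <- f1; f2$b <- 0.02
  expect_lt(gompertz_remaining_le(f2), gompertz_remaining_le(f1))
})

test_that("small-sample MLE matches a brute-force grid search", {
  d <- sim_gompertz(150, seed = 5, cens_lo = 60, cens_hi = 80)  # no censoring
  d$entry_age <- pmin(d$entry_age, 45)  # near-zero truncation
  fit <- fit_gompertz(d, min_events = 10)
  grid_b <- exp(seq(log(fit$b) - 0.5, log(fit$b) + 0.5, length.out = 41))
  grid_g <- seq(fit$g - 0.05, fit$g + 0.05, length.out = 41)
  nll <- function(b, g) elitemort:::gompertz_nll(
    c(log(b), g), u = d$entry_age - 45, v = d$exit_age - 45,
    delta = as.numeric(d$event), x = rep(0, nrow(d)))
  vals <- outer(grid_b, grid_g, Vectorize(nll))
  best <- which(vals == min(vals), arr.ind = TRUE)
  expect_lt(abs(log(grid_b[best[1]]) - log(fit$b)), 0.05)
  expect_lt(abs(grid_g[best[2]] - fit$g), 0.01)
})

test_that("bootstrap with B = 1 is the single re-estimate", {
  d <- sim_gompertz(800, seed = 6)
  bs <- bootstrap_le(d, B = 1, seed = 7)
  expect_equal(bs$ci[1], bs$ci[2])
  expect_equal(bs$ci[1], bs$draws[1])
})

test_that("duplicating the dataset narrows the bootstrap CI by about 1/sqrt(2)", {
  d <- sim_gompertz(700, seed = 8)
  d2 <- rbind(d, d)
  b1 <- bootstrap_le(d, B = 200, seed = 9)
  b2 <- bootstrap_le(d2, B = 200, seed = 9)
  w1 <- diff(b1$ci); w2 <- diff(b2$ci)
  expect_lt(abs(w2 / w1 - 1 / sqrt(2)), 0.2 / sqrt(2))
})

test_that("bootstrap is reproducible for a fixed seed", {
  d <- sim_gompertz(500, seed = 10)
  b1 <- bootstrap_le(d, B = 25, seed = 11)
  b2 <- bootstrap_le(d, B = 25, seed = 11)
  expect_identical(b1$draws, b2$draws)
})

test_that("rising male fraction raises pooled population LE when females live longer", {
  sc <- synthetic_scenario(years = c(1950, 1970), table_spacing = 1,
                           n_politicians = 10)
  surf <- make_surface(sc, spacing = 1)$surface
  # females have lower hazard in the default scenario
  le_mostly_female <- pooled_population_le(surf, c(1955, 1964), 45, 0.2)
  le_mostly_male <- pooled_population_le(surf, c(1955, 1964), 45, 0.9)
  expect_gt(le_mostly_female, le_mostly_male)
})
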