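# Life-table ingestion, interpolation, and remaining life expectancy.

test_that("a small HMD-style file parses into a validated surface", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Year,Age,qx",
               "1900,0,0.1",
               "1900,1,0.05",
               "1900,2,1.0"), path)
  s <- read_lifetable(path, sex = "male", country = "Toyland")
  expect_s3_class(s, "lifetable_surface")
  expect_equal(max(s$data$age), 2)
  expect_equal(qx_lookup(s, "male", 1900, 0), 0.1)
  expect_equal(qx_lookup(s, "male", 1900, 2), 1.0)
})

test_that("rows with qx outside [0,1] are reported and loading fails", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Year,Age,qx",
               "1900,0,0.1",
               "1900,1,1.2"), path)
  expect_error(read_lifetable(path, sex = "male"), "qx outside")
})

test_that("missing columns and non-contiguous ages are rejected", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Year,qx", "1900,0.1"), path)
  expect_error(read_lifetable(path, sex = "male"), "required column")
  path2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Year,Age,qx", "1900,0,0.1", "1900,2,0.2"), path2)
  expect_error(read_lifetable(path2, sex = "male"), "contiguous")
})

test_that("a generated surface round-trips through the HMD dialect", {
  sc <- synthetic_scenario(years = c(1950, 1980), table_spacing = 10,
                           n_politicians = 10)
  surf <- make_surface(sc)$surface
  path <- withr::local_tempfile(fileext = ".csv")
  write_lifetable(surf, path)
  back <- read_lifetable(path, country = surf$country)
  m <- merge(surf$data, back$data, by = c("sex", "year", "age"))
  expect_equal(nrow(m), nrow(surf$data))
  expect_lt(max(abs(m$qx.x - m$qx.y)), 1e-8)
})

test_that("interpolation is the identity on an already-annual surface", {
  sc <- synthetic_scenario(years = c(1960, 1975), table_spacing = 1,
                           n_politicians = 10)
  surf <- make_surface(sc, spacing = 1)$surface
  out <- interpolate_annual(surf, diagnostics = FALSE)
  m <- merge(surf$data, out$data, by = c("sex", "year", "age"))
  z_in <- log(-log(1 - m$qx.x)); z_out <- log(-log(1 - m$qx.y))
  expect_lt(max(abs(z_in - z_out)), 1e-6)
})

test_that("a 10-yearly surface from a smooth log-hazard is recovered annually", {
  sc <- synthetic_scenario(years = c(1900, 2000), table_spacing = 10,
                           n_politicians = 10)
  gapped <- make_surface(sc, spacing = 10)$surface
  truth <- make_surface(sc, spacing = 1)$surface
  interp <- interpolate_annual(gapped)
  m <- merge(interp$data, truth$data, by = c("sex", "year", "age"),
             suffixes = c("_i", "_t"))
  expect_equal(nrow(m), nrow(truth$data))
  expect_lt(max(abs(m$qx_i - m$qx_t) / m$qx_t), 0.02)
  # observed years reproduced
  obs <- merge(interp$data, gapped$data, by = c("sex", "year", "age"),
               suffixes = c("_i", "_o"))
  expect_lt(max(abs(obs$qx_i - obs$qx_o)), 1e-4)
  # residual report exists and is well-behaved
  rep <- interpolation_report(interp)
  expect_true(all(c("skewness", "n_outliers") %in% names(rep)))
})

test_that("two-year input interpolates monotonically on the transformed scale", {
  grid <- expand.grid(sex = "male", year = c(1900, 1910), age = 0:50,
                      stringsAsFactors = FALSE)
  grid$qx <- ifelse(grid$year == 1900, 0.02, 0.01) * (1 + grid$age / 50)
  s <- lifetable_surface(grid)
  out <- interpolate_annual(s, diagnostics = FALSE)
  z <- function(q) log(-log(1 - q))
  for (a in c(0, 25, 50)) {
    d <- out$data[out$data$age == a]
    d <- d[order(d$year)]
    zs <- z(d$qx)
    expect_true(all(diff(zs) <= 1e-12) || all(diff(zs) >= -1e-12))
    expect_true(all(zs <= max(zs[c(1, length(zs))]) + 1e-9 &
                      zs >= min(zs[c(1, length(zs))]) - 1e-9))
  }
})

test_that("interpolation refuses single-year input", {
  grid <- expand.grid(sex = "male", year = 1900, age = 0:10,
                      stringsAsFactors = FALSE)
  grid$qx <- 0.02
  expect_error(interpolate_annual(lifetable_surface(grid)), "interpolate")
})

test_that("remaining life expectancy follows the uniform-deaths convention", {
  # qx = 1 at the queried age forces e = 0.5
  grid <- expand.grid(sex = "male", year = 2000, age = 0:5,
                      stringsAsFactors = FALSE)
  grid$qx <- c(0.1, 0.1, 1, 1, 1, 1)
  s <- lifetable_surface(grid)
  expect_equal(remaining_life_expectancy(s, "male", 2000, 2), 0.5)
  # constant qx: geometric closed form (1-q)/q + 0.5 at large omega
  q <- 0.05
  grid2 <- expand.grid(sex = "male", year = 2000, age = 0:400,
                       stringsAsFactors = FALSE)
  grid2$qx <- q
  s2 <- lifetable_surface(grid2)
  expect_equal(remaining_life_expectancy(s2, "male", 2000, 0),
               (1 - q) / q + 0.5, tolerance = 1e-6)
})

test_that("life-table e(45) matches the generator's continuous truth", {
  sc <- synthetic_scenario(years = c(1950, 1990), table_spacing = 1,
                           n_politicians = 10)
  ms <- make_surface(sc, spacing = 1)
  for (i in seq_len(nrow(ms$manifest$true_e45))) {
    row <- ms$manifest$true_e45[i]
    e_table <- remaining_life_expectancy(ms$surface, row$sex, row$year, 45)
    expect_lt(abs(e_table - row$e45_true), 0.05)
  }
})

test_that("e(x) decreases when all qx are shifted up", {
  sc <- synthetic_scenario(years = c(1950, 1960), table_spacing = 1,
                           n_politicians = 10)
  surf <- make_surface(sc, spacing = 1)$surface
  e0 <- remaining_life_expectancy(surf, "male", 1955, 45)
  bumped <- surf$data
  bumped$qx <- pmin(bumped$qx * 1.2, 1)
  e1 <- remaining_life_expectancy(lifetable_surface(bumped), "male", 1955, 45)
  expect_lt(e1, e0)
})

test_that("pooled population LE is linear in the male fraction", {
  sc <- synthetic_scenario(years = c(1950, 1970), table_spacing = 1,
                           n_politicians = 10)
  surf <- make_surface(sc, spacing = 1)$surface
  w <- c(1955, 1964)
  em <- pooled_population_le(surf, w, 45, 1)
  ef <- pooled_population_le(surf, w, 45, 0)
  # male-only equals the male window mean
  yrs <- 1955:1964
  expect_equal(em, mean(sapply(yrs, function(y)
    remaining_life_expectancy(surf, "male", y, 45))))
  for (p in c(0.25, 0.5, 0.8)) {
    expect_equal(pooled_population_le(surf, w, 45, p),
                 p * em + (1 - p) * ef, tolerance = 1e-12)
  }
  # identical tables for both sexes make the mix irrelevant
  flat <- flat_surface(qx_male = 0.03, qx_female = 0.03, years = 1990:1999)
  expect_equal(pooled_population_le(flat, c(1990, 1999), 45, 0.5),
               pooled_population_le(flat, c(1990, 1999), 45, 1))
})

test_that("standard-population weights load, normalize and band correctly", {
  w <- read_standard_weights()
  expect_equal(sum(w$weight), 1, tolerance = 1e-12)
  expect_true(all(w$weight >= 0))
  expect_equal(w$age_lo[1], 0)
  expect_true(is.infinite(w$age_hi[nrow(w)]))
})
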