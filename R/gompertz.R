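# Absolute inequality: Gompertz proportional-hazards fits on the age scale
# within consecutive 10-year calendar windows, remaining life expectancy at
# 45, and gaps versus the gender-pooled general population with bootstrap
# confidence intervals.
#
# The hazard is parameterized at reference age 45,
#   h(a) = b * exp(g * (a - 45)) * exp(beta_sex * female),
# so that b is the hazard level near the centre of the data (entry ages
# cluster around 45) — a pure reparameterization that keeps the optimizer
# well conditioned. The likelihood is left-truncated at the age of entry
# into the window and right-censored.

# E(t) = (exp(g t) - 1) / g, the integrated relative hazard; series form
# near g = 0 keeps the exponential-lifetime limit exact. Vectorized in t
# (g is always scalar).
gomp_E <- function(t, g) {
  if (abs(g) < 1e-10) return(t * (1 + g * t / 2))
  expm1(g * t) / g
}

gomp_E_dg <- function(t, g) {
  if (abs(g) < 1e-7) return(t^2 / 2 + g * t^3 / 3)
  (t * exp(g * t) - gomp_E(t, g)) / g
}

#' Slice cohort follow-up into a 10-year calendar window on the age scale
#'
#' Each record contributes the part of its follow-up that intersects the
#' window: entry age at the later of office entry and the window start,
#' exit age at the earliest of death, censoring and the window end, and an
#' event flag for deaths inside the window. Ages are exact (days/365.25).
#' Consecutive windows partition each record's follow-up exactly.
#'
#' @param records retained cohort data.table.
#' @param window integer `c(start_year, end_year)` (inclusive; a 10-year
#'   window is `c(1950, 1959)`).
#' @param last_year last calendar year with life-table data (censoring).
#' @return data.table: `id, sex, entry_age, exit_age, event`.
#' @export
window_slices <- function(records, window, last_year) {
  rec <- data.table::as.data.table(records)
  fb <- followup_bounds(rec, last_year)
  w_lo <- jan1(window[1]); w_hi <- jan1(window[2] + 1L)
  entry <- pmax(fb$start, w_lo)
  exit <- pmin(fb$end, w_hi)
  keep <- exit > entry
  if (!any(keep)) {
    return(data.table::data.table(id = character(0), sex = character(0),
                                  entry_age = numeric(0),
                                  exit_age = numeric(0), event = logical(0)))
  }
  event <- fb$died & fb$end < w_hi & fb$end > entry
  data.table::data.table(
    id = rec$id[keep], sex = rec$sex[keep],
    entry_age = as.numeric(entry[keep] - rec$birth_date[keep]) / DAYS_PER_YEAR,
    exit_age = as.numeric(exit[keep] - rec$birth_date[keep]) / DAYS_PER_YEAR,
    event = event[keep]
  )
}

gompertz_nll <- function(theta, u, v, delta, x, ref = 45) {
  has_sex <- length(theta) == 3L
  log_b <- theta[1]; g <- theta[2]
  beta <- if (has_sex) theta[3] else 0
  B <- exp(log_b + beta * x)
  Hdiff <- B * (gomp_E(v, g) - gomp_E(u, g))
  loghaz <- log_b + beta * x + g * v
  -sum(delta * loghaz) + sum(Hdiff)
}

gompertz_nll_grad <- function(theta, u, v, delta, x, ref = 45) {
  has_sex <- length(theta) == 3L
  log_b <- theta[1]; g <- theta[2]
  beta <- if (has_sex) theta[3] else 0
  B <- exp(log_b + beta * x)
  Ev <- gomp_E(v, g); Eu <- gomp_E(u, g)
  dEv <- gomp_E_dg(v, g); dEu <- gomp_E_dg(u, g)
  Hdiff <- B * (Ev - Eu)
  d_logb <- -sum(delta) + sum(Hdiff)
  d_g <- -sum(delta * v) + sum(B * (dEv - dEu))
  if (has_sex) {
    d_beta <- -sum(delta * x) + sum(x * Hdiff)
    c(d_logb, d_g, d_beta)
  } else c(d_logb, d_g)
}

#' Fit a left-truncated Gompertz proportional-hazards model
#'
#' Maximizes the left-truncated, right-censored Gompertz log-likelihood on
#' the age scale. With both sexes present (and `sex_covariate = TRUE`) a
#' proportional log hazard ratio for females versus males is included.
#'
#' @param data data.table from [window_slices()].
#' @param min_events windows with fewer events are reported unestimable
#'   (default 30).
#' @param sex_covariate include a female/male proportional-hazards term
#'   when both sexes are present (default TRUE).
#' @param start optional starting values `c(log_b, g[, beta_sex])`.
#' @return object of class `gompertz_fit` with elements `b` (hazard at age
#'   45), `g` (log-hazard slope per year of age), `beta_sex` (log HR female
#'   vs male, or NA), `vcov` (observed-information covariance of
#'   `(log_b, g[, beta_sex])`), `n_at_risk`, `n_events`, `estimable`.
#' @export
fit_gompertz <- function(data, min_events = 30, sex_covariate = TRUE,
                         start = NULL) {
  data <- data.table::as.data.table(data)
  n <- nrow(data)
  n_events <- sum(data$event)
  out <- structure(list(b = NA_real_, g = NA_real_, beta_sex = NA_real_,
                        vcov = NULL, n_at_risk = n, n_events = n_events,
                        estimable = FALSE, loglik = NA_real_,
                        has_sex = FALSE, diagnostics = NULL),
                   class = "gompertz_fit")
  if (n == 0 || n_events < min_events) {
    out$diagnostics <- paste0("too few events (", n_events, " < ",
                              min_events, ")")
    return(out)
  }
  u <- data$entry_age - 45
  v <- data$exit_age - 45
  delta <- as.numeric(data$event)
  has_sex <- sex_covariate && length(unique(data$sex)) > 1L
  x <- if (has_sex) as.numeric(data$sex == "female") else rep(0, n)
  if (is.null(start)) {
    rate0 <- n_events / sum(v - u)
    start <- c(log(rate0), 0.08)
    if (has_sex) start <- c(start, 0)
  }
  fit <- try(stats::optim(start, gompertz_nll, gr = gompertz_nll_grad,
                          u = u, v = v, delta = delta, x = x,
                          method = "BFGS",
                          control = list(maxit = 500, reltol = 1e-12)),
             silent = TRUE)
  if (inherits(fit, "try-error") || fit$convergence != 0) {
    out$diagnostics <- "optimizer failed to converge"
    return(out)
  }
  if (abs(fit$par[2]) > 1) {
    out$diagnostics <- "age slope g at implausible bound (|g| > 1)"
    return(out)
  }
  hess <- try(stats::optimHess(fit$par, gompertz_nll, gr = gompertz_nll_grad,
                               u = u, v = v, delta = delta, x = x),
              silent = TRUE)
  vc <- if (!inherits(hess, "try-error")) try(solve(hess), silent = TRUE)
        else NULL
  out$b <- exp(fit$par[1])
  out$g <- fit$par[2]
  out$beta_sex <- if (has_sex) fit$par[3] else NA_real_
  out$has_sex <- has_sex
  out$vcov <- if (!inherits(vc, "try-error")) vc else NULL
  out$loglik <- -fit$value
  out$estimable <- TRUE
  out
}

#' @export
print.gompertz_fit <- function(x, ...) {
  if (!x$estimable) {
    cat("<gompertz_fit> unestimable: ", x$diagnostics, "\n", sep = "")
  } else {
    cat("<gompertz_fit> b(45)=", signif(x$b, 4), " g=", signif(x$g, 4),
        if (x$has_sex) paste0(" beta_sex=", signif(x$beta_sex, 4)) else "",
        " events=", x$n_events, "/", x$n_at_risk, "\n", sep = "")
  }
  invisible(x)
}

# survival-integral for one sex: S(t) = exp(-B (E(t0 + t) - E(t0))),
# integrated by adaptive quadrature, truncated where S < 1e-12.
gomp_le_one <- function(B, g, t0 = 0) {
  target <- -log(1e-12)  # cumulative hazard at truncation
  Ht <- target + B * gomp_E(t0, g)
  if (g < -1e-10 && B * (-1 / g) - B * gomp_E(t0, g) < target) {
    # hazard decays so fast a positive fraction never dies
    warning("Gompertz fit implies an improper survival function (g < 0); ",
            "remaining life expectancy is infinite")
    return(Inf)
  }
  upper <- if (abs(g) < 1e-10) Ht / B else log1p(g * Ht / B) / g
  upper <- upper - t0
  S <- function(tt) exp(-B * (gomp_E(t0 + tt, g) - gomp_E(t0, g)))
  stats::integrate(S, 0, upper, rel.tol = 1e-10, subdivisions = 1000L)$value
}

#' Remaining life expectancy implied by a Gompertz fit
#'
#' Integrates the fitted survival function from the reference age,
#' `e(age) = int_0^inf exp(-(B/g)(exp(g u) - 1)) du` at `age = 45`, with
#' `B = b * exp(beta_sex)` for females, and mixes the two sexes with the
#' cohort sex proportions. Adaptive quadrature truncated where survival
#' falls below 1e-12; the g -> 0 limit (exponential lifetime, e = 1/B) is
#' handled by the same integral.
#'
#' @param fit a [fit_gompertz()] result.
#' @param age age from which remaining life expectancy is computed
#'   (default 45, the reference age).
#' @param male_fraction proportion male used to mix the sexes; ignored for
#'   fits without a sex term.
#' @return years of remaining life expectancy.
#' @export
gompertz_remaining_le <- function(fit, age = 45, male_fraction = 1) {
  if (!fit$estimable) return(NA_real_)
  t0 <- age - 45
  if (!fit$has_sex) return(gomp_le_one(fit$b, fit$g, t0))
  e_m <- gomp_le_one(fit$b, fit$g, t0)
  e_f <- gomp_le_one(fit$b * exp(fit$beta_sex), fit$g, t0)
  male_fraction * e_m + (1 - male_fraction) * e_f
}

exposure_male_fraction <- function(data) {
  py <- data$exit_age - data$entry_age
  sum(py[data$sex == "male"]) / sum(py)
}

#' Bootstrap confidence interval for window life expectancy
#'
#' Resamples individuals (not person-year slices) with replacement,
#' refits the Gompertz model and recomputes remaining life expectancy; the
#' CI is the 2.5/97.5 percentile of the resampled estimates. Reproducible
#' for a fixed seed. Flagged unreliable when more than 10% of resamples are
#' unestimable.
#'
#' @param data data.table from [window_slices()].
#' @param B bootstrap replicates (default 1000).
#' @param seed RNG seed.
#' @param age reference age (default 45).
#' @param male_fraction fixed sex mix for the life-expectancy mixture; when
#'   `NULL` (default) each resample uses its own exposure-weighted mix.
#' @param min_events,sex_covariate passed to [fit_gompertz()].
#' @return list with `ci` (2.5/97.5 percentiles), `draws`, `n_failed`,
#'   `reliable`.
#' @export
bootstrap_le <- function(data, B = 1000, seed = 1, age = 45,
                         male_fraction = NULL, min_events = 30,
                         sex_covariate = TRUE) {
  data <- data.table::as.data.table(data)
  set.seed(seed)
  n <- nrow(data)
  draws <- rep(NA_real_, B)
  for (i in seq_len(B)) {
    d <- data[sample.int(n, n, replace = TRUE)]
    f <- suppressWarnings(
      fit_gompertz(d, min_events = min_events, sex_covariate = sex_covariate)
    )
    if (f$estimable) {
      mf <- if (is.null(male_fraction)) exposure_male_fraction(d)
            else male_fraction
      draws[i] <- suppressWarnings(gompertz_remaining_le(f, age, mf))
    }
  }
  n_failed <- sum(!is.finite(draws))
  ok <- draws[is.finite(draws)]
  ci <- if (length(ok) > 0) {
    stats::quantile(ok, c(0.025, 0.975), names = FALSE)
  } else c(NA_real_, NA_real_)
  list(ci = ci, draws = draws, n_failed = n_failed,
       reliable = n_failed <= 0.1 * B)
}

default_windows <- function(first_year, last_year) {
  start <- 10L * ceiling(first_year / 10)
  starts <- seq(start, last_year - 9L, by = 10L)
  lapply(starts, function(s) c(s, s + 9L))
}

#' Life-expectancy gaps between the cohort and its population by window
#'
#' For each consecutive 10-year window: fits the Gompertz model to the
#' cohort person-time in the window, derives remaining life expectancy at
#' `age` mixed by the window's exposure-weighted male fraction, bootstraps
#' the cohort to get a 95% CI, and subtracts the gender-pooled population
#' remaining life expectancy (period life tables averaged over the window,
#' pooled with the same male fraction). Positive gaps mean the cohort lives
#' longer. Windows below the event floor are emitted with missing
#' estimates.
#'
#' @param records retained cohort data.table.
#' @param surface an annual [lifetable_surface()].
#' @param windows list of `c(start, end)` windows; default: consecutive
#'   10-year windows from the first decade boundary at or after the first
#'   office year to the last life-table year.
#' @param age reference age (default 45).
#' @param boot_B bootstrap replicates per window (default 1000).
#' @param seed RNG seed (incremented per window).
#' @param min_events,sex_covariate passed to [fit_gompertz()].
#' @return data.table: `window_start, window_end, n, events, male_fraction,
#'   le_politicians, le_lo, le_hi, le_population, gap, gap_lo, gap_hi,
#'   estimable, b, g, beta_sex`.
#' @export
le_gap_series <- function(records, surface, windows = NULL, age = 45,
                          boot_B = 1000, seed = 1, min_events = 30,
                          sex_covariate = TRUE) {
  rec <- data.table::as.data.table(records)
  yrs <- surface_years(surface)
  last_year <- max(yrs)
  if (is.null(windows)) {
    first <- max(min(year_of(rec$office_date)), min(yrs))
    windows <- default_windows(first, last_year)
  }
  rows <- vector("list", length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    d <- window_slices(rec, w, last_year)
    fit <- fit_gompertz(d, min_events = min_events,
                        sex_covariate = sex_covariate)
    mf <- if (nrow(d) > 0) exposure_male_fraction(d) else NA_real_
    if (fit$estimable) {
      le_pol <- suppressWarnings(gompertz_remaining_le(fit, age, mf))
      bs <- bootstrap_le(d, B = boot_B, seed = seed + i, age = age,
                         male_fraction = NULL, min_events = min_events,
                         sex_covariate = sex_covariate)
      le_pop <- pooled_population_le(surface, w, age, mf)
      rows[[i]] <- data.table::data.table(
        window_start = w[1], window_end = w[2], n = fit$n_at_risk,
        events = fit$n_events, male_fraction = mf,
        le_politicians = le_pol, le_lo = bs$ci[1], le_hi = bs$ci[2],
        le_population = le_pop, gap = le_pol - le_pop,
        gap_lo = bs$ci[1] - le_pop, gap_hi = bs$ci[2] - le_pop,
        estimable = TRUE, reliable_ci = bs$reliable,
        b = fit$b, g = fit$g, beta_sex = fit$beta_sex
      )
    } else {
      rows[[i]] <- data.table::data.table(
        window_start = w[1], window_end = w[2],
        n = nrow(d), events = sum(d$event), male_fraction = mf,
        le_politicians = NA_real_, le_lo = NA_real_, le_hi = NA_real_,
        le_population = NA_real_, gap = NA_real_, gap_lo = NA_real_,
        gap_hi = NA_real_, estimable = FALSE, reliable_ci = NA,
        b = NA_real_, g = NA_real_, beta_sex = NA_real_
      )
    }
  }
  data.table::rbindlist(rows)
}
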