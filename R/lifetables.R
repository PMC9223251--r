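# Period life tables: ingestion, annual interpolation, and remaining life
# expectancy. The surface is the population comparator for every downstream
# stage (expected deaths, direct standardization, pooled life expectancy).

#' Construct a life-table surface
#'
#' A surface holds conditional one-year death probabilities `qx` indexed by
#' (sex, calendar year, integer age) for one country. Ages must form a
#' contiguous run from 0 to the terminal (open) age within every
#' (sex, year); `qx` at the terminal age is treated as 1 over the closing
#' interval when expectancies are computed.
#'
#' @param data data.frame with columns `sex` ("male"/"female"), `year`
#'   (integer), `age` (integer), `qx` (probability in \[0, 1\]).
#' @param country country label.
#' @param annual logical; `TRUE` when every calendar year between the first
#'   and last is populated (set by [interpolate_annual()]).
#' @return object of class `lifetable_surface`.
#' @export
lifetable_surface <- function(data, country = "synthetic", annual = NA) {
  dt <- data.table::as.data.table(data)
  required <- c("sex", "year", "age", "qx")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0) {
    stop("life table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, list(sex = as.character(sex), year = as.integer(year),
                  age = as.integer(age), qx = as.numeric(qx))]
  bad_sex <- setdiff(unique(dt$sex), c("male", "female"))
  if (length(bad_sex) > 0) {
    stop("unknown sex code(s): ", paste(bad_sex, collapse = ", "))
  }
  bad <- which(!is.finite(dt$qx) | dt$qx < 0 | dt$qx > 1)
  if (length(bad) > 0) {
    stop("qx outside [0, 1] in ", length(bad), " row(s); first offending rows: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  data.table::setkeyv(dt, c("sex", "year", "age"))
  # contiguity check per (sex, year)
  chk <- dt[, list(contiguous = identical(age, seq(min(age), max(age))),
                   min_age = min(age)), by = c("sex", "year")]
  if (any(!chk$contiguous | chk$min_age != 0L)) {
    off <- chk[!chk$contiguous | chk$min_age != 0L]
    stop("ages are not a contiguous 0..omega run for sex=", off$sex[1],
         " year=", off$year[1])
  }
  if (is.na(annual)) {
    annual <- dt[, {
      ys <- sort(unique(year))
      identical(ys, seq(min(ys), max(ys)))
    }, by = "sex"][, all(V1)]
  }
  structure(
    list(country = country, data = dt, annual = isTRUE(annual),
         cache = new.env(parent = emptyenv())),
    class = "lifetable_surface"
  )
}

#' @export
print.lifetable_surface <- function(x, ...) {
  yrs <- range(x$data$year)
  cat("<lifetable_surface> country=", x$country,
      " sexes=", paste(sort(unique(x$data$sex)), collapse = "/"),
      " years=", yrs[1], "-", yrs[2],
      " ages=0-", max(x$data$age),
      if (x$annual) " (annual)" else " (gapped)", "\n", sep = "")
  invisible(x)
}

#' Calendar years present on a surface
#' @param surface a [lifetable_surface()].
#' @param sex optional sex restriction.
#' @return sorted integer vector of years.
#' @export
surface_years <- function(surface, sex = NULL) {
  dt <- surface$data
  if (!is.null(sex)) {
    sx <- sex
    dt <- dt[dt$sex == sx]
  }
  sort(unique(dt$year))
}

surface_omega <- function(surface) max(surface$data$age)

# Dense array cache for fast vectorized qx lookup on annual surfaces.
surface_index <- function(surface) {
  cache <- surface$cache
  if (!is.null(cache$arr)) return(cache)
  dt <- surface$data
  y0 <- min(dt$year); y1 <- max(dt$year); om <- max(dt$age)
  arr <- array(NA_real_, dim = c(2L, y1 - y0 + 1L, om + 1L))
  si <- ifelse(dt$sex == "male", 1L, 2L)
  arr[cbind(si, dt$year - y0 + 1L, dt$age + 1L)] <- dt$qx
  cache$arr <- arr; cache$y0 <- y0; cache$y1 <- y1; cache$omega <- om
  cache
}

#' Look up death probabilities on a surface
#'
#' Vectorized over (sex, year, age). Ages beyond the terminal age return 1
#' (death certain in the open interval). Cells absent from the surface
#' (year or sex not covered) raise an error naming the first missing cell.
#'
#' @param surface a [lifetable_surface()].
#' @param sex,year,age vectors (recycled to common length).
#' @return numeric vector of qx.
#' @export
qx_lookup <- function(surface, sex, year, age) {
  idx <- surface_index(surface)
  n <- max(length(sex), length(year), length(age))
  sex <- rep_len(sex, n); year <- rep_len(as.integer(year), n)
  age <- rep_len(as.integer(age), n)
  si <- ifelse(sex == "male", 1L, 2L)
  out <- numeric(n)
  over <- age > idx$omega
  out[over] <- 1
  ok <- !over
  if (any(ok)) {
    yr <- year[ok]
    if (any(yr < idx$y0 | yr > idx$y1)) {
      j <- which(yr < idx$y0 | yr > idx$y1)[1]
      stop("no life-table data for year ", yr[j],
           " (surface covers ", idx$y0, "-", idx$y1, ")")
    }
    v <- idx$arr[cbind(si[ok], yr - idx$y0 + 1L, age[ok] + 1L)]
    if (anyNA(v)) {
      j <- which(is.na(v))[1]
      stop("life-table cell missing: sex=", sex[ok][j], " year=", yr[j],
           " age=", age[ok][j],
           if (!surface$annual) " (surface not interpolated to annual years)" else "")
    }
    out[ok] <- v
  }
  out
}

#' Read an HMD-style 1x1 period life table
#'
#' Accepts whitespace- or comma-delimited files with at least `Year`, `Age`
#' and `qx` columns (case-insensitive); the terminal open age may be written
#' as e.g. `110+`. A `Sex` column is used when present, otherwise the `sex`
#' argument labels the whole file.
#'
#' @param path file path.
#' @param sex sex label for files without a `Sex` column.
#' @param country country label for the resulting surface.
#' @return a [lifetable_surface()].
#' @export
read_lifetable <- function(path, sex = NULL, country = "unknown") {
  if (!file.exists(path)) stop("life-table file not found: ", path)
  dt <- data.table::fread(path, header = TRUE)
  names(dt) <- tolower(names(dt))
  required <- c("year", "age", "qx")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0) {
    stop("life-table file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"sex" %in% names(dt)) {
    if (is.null(sex)) stop("file has no Sex column; supply `sex=`")
    dt$sex <- sex
  }
  age_chr <- sub("\\+$", "", as.character(dt$age))
  age <- suppressWarnings(as.integer(age_chr))
  if (anyNA(age)) {
    stop("unparseable Age value(s), e.g. '", dt$age[which(is.na(age))[1]], "'")
  }
  qx <- suppressWarnings(as.numeric(dt$qx))
  bad <- which(is.na(qx) | qx < 0 | qx > 1)
  if (length(bad) > 0) {
    stop("rejected ", length(bad), " row(s) with qx outside [0,1] or missing; ",
         "first at file row ", bad[1] + 1L, " (Year=", dt$year[bad[1]],
         ", Age=", dt$age[bad[1]], ", qx=", dt$qx[bad[1]], ")")
  }
  lifetable_surface(
    data.frame(sex = dt$sex, year = dt$year, age = age, qx = qx),
    country = country
  )
}

#' Write a surface in the same HMD-style layout the reader accepts
#'
#' @param surface a [lifetable_surface()].
#' @param path output path.
#' @param digits decimal digits for qx.
#' @return `path`, invisibly.
#' @export
write_lifetable <- function(surface, path, digits = 8) {
  dt <- data.table::copy(surface$data)
  om <- max(dt$age)
  out <- data.table::data.table(
    Sex = dt$sex, Year = dt$year,
    Age = ifelse(dt$age == om, paste0(om, "+"), as.character(dt$age)),
    qx = formatC(dt$qx, digits = digits, format = "f")
  )
  data.table::fwrite(out, path, sep = ",")
  invisible(path)
}

#' Interpolate a gapped life-table surface to annual resolution
#'
#' Early historical tables are often published only every 5 or 10 calendar
#' years. This fills every intermediate year by two-dimensional grid
#' interpolation on the log cumulative-hazard scale
#' `z = log(-log(1 - qx))`: ages are already complete within each observed
#' year, so the tensor-product interpolant reduces to a natural cubic spline
#' across calendar years at each integer age. Observed years are reproduced
#' exactly and back-transformed values lie in (0, 1] automatically.
#' Extrapolation beyond the observed year range is refused.
#'
#' A diagnostic residual report (observed cells against a cross-validated
#' tensor-product smooth over age and year, with skewness and outlier
#' counts) is attached; retrieve it with [interpolation_report()].
#'
#' @param surface a [lifetable_surface()] with at least two distinct years
#'   per sex.
#' @param diagnostics logical; fit the smooth-surface residual report
#'   (default `TRUE`).
#' @return an annual [lifetable_surface()].
#' @export
interpolate_annual <- function(surface, diagnostics = TRUE) {
  dt <- surface$data
  pieces <- list()
  reports <- list()
  for (sx in sort(unique(dt$sex))) {
    d <- dt[dt$sex == sx]
    yrs <- sort(unique(d$year))
    if (length(yrs) < 2) {
      stop("cannot interpolate: only ", length(yrs),
           " calendar year(s) for sex=", sx)
    }
    om <- min(d[, list(om = max(age)), by = "year"]$om)
    d <- d[d$age <= om]
    z <- matrix(NA_real_, nrow = om + 1L, ncol = length(yrs))
    z[cbind(d$age + 1L, match(d$year, yrs))] <- qx_to_z(d$qx)
    annual_years <- seq(min(yrs), max(yrs))
    zi <- t(apply(z, 1, function(row) {
      stats::spline(x = yrs, y = row, xout = annual_years,
                    method = "natural")$y
    }))
    qx_new <- z_to_qx(zi)
    qx_new <- clamp01(qx_new)
    pieces[[sx]] <- data.table::data.table(
      sex = sx,
      year = rep(annual_years, each = om + 1L),
      age = rep(0:om, times = length(annual_years)),
      qx = as.vector(qx_new)
    )
    if (diagnostics) {
      gd <- data.frame(age = d$age, year = d$year, z = qx_to_z(d$qx))
      k_age <- min(20L, length(unique(gd$age)) - 1L)
      k_year <- min(10L, length(yrs))
      fit <- mgcv::gam(z ~ te(age, year, k = c(k_age, k_year)), data = gd)
      r <- stats::residuals(fit)
      s <- stats::sd(r)
      reports[[sx]] <- data.table::data.table(
        sex = sx, n_cells = length(r), sd_resid = s,
        skewness = mean((r - mean(r))^3) / s^3,
        n_outliers = sum(abs(r - mean(r)) > 3 * s)
      )
    }
  }
  out <- lifetable_surface(data.table::rbindlist(pieces),
                           country = surface$country, annual = TRUE)
  if (diagnostics) {
    attr(out, "interpolation_report") <- data.table::rbindlist(reports)
  }
  out
}

#' Residual diagnostics from [interpolate_annual()]
#' @param surface an interpolated surface.
#' @return data.table of per-sex residual summaries, or `NULL`.
#' @export
interpolation_report <- function(surface) attr(surface, "interpolation_report")

#' Remaining life expectancy from a period life table
#'
#' Computes `e(x) = sum_k S_k + 0.5`, where `S_k` is the probability of
#' surviving `k` further whole years from exact age `x`, under the
#' uniform-deaths convention (average half a year lived in the year of
#' death, including the terminal open interval where `qx` is taken as 1).
#'
#' @param surface a [lifetable_surface()].
#' @param sex "male" or "female".
#' @param year calendar year (must be present on the surface).
#' @param age integer exact age.
#' @return remaining life expectancy in years.
#' @export
remaining_life_expectancy <- function(surface, sex, year, age) {
  stopifnot(length(sex) == 1, length(year) == 1, length(age) == 1)
  dt <- surface$data
  sx <- sex; yr <- as.integer(year)
  d <- dt[dt$sex == sx & dt$year == yr]
  if (nrow(d) == 0) {
    stop("no life-table data for sex=", sex, " year=", year,
         if (!surface$annual) "; interpolate the surface first" else "")
  }
  om <- max(d$age)
  if (age > om) stop("age ", age, " exceeds terminal age ", om)
  qx <- d$qx[match(age:om, d$age)]
  qx[length(qx)] <- 1  # open terminal interval
  sum(cumprod(1 - qx)) + 0.5
}

#' Gender-pooled population remaining life expectancy over a year window
#'
#' Averages single-year remaining life expectancies over the calendar years
#' of a window, separately by sex, then mixes them with the cohort's male
#' fraction. Used as the population comparator for life-expectancy gaps.
#'
#' @param surface an annual [lifetable_surface()].
#' @param window integer vector `c(start, end)`, inclusive calendar years.
#' @param age exact age (default 45).
#' @param male_fraction proportion male in \[0, 1\].
#' @return pooled remaining life expectancy in years.
#' @export
pooled_population_le <- function(surface, window, age = 45, male_fraction) {
  stopifnot(male_fraction >= 0, male_fraction <= 1)
  years <- seq(window[1], window[2])
  years <- intersect(years, surface_years(surface))
  if (length(years) == 0) stop("window contains no life-table years")
  em <- mean(vapply(years, function(y)
    remaining_life_expectancy(surface, "male", y, age), numeric(1)))
  ef <- mean(vapply(years, function(y)
    remaining_life_expectancy(surface, "female", y, age), numeric(1)))
  male_fraction * em + (1 - male_fraction) * ef
}

#' World Standard Population weights
#'
#' Loads age-band weights for direct standardization. The packaged default
#' is the WHO World Standard Population in 5-year bands 0-4 .. 85+;
#' weights are normalized to sum to one on load.
#'
#' @param path optional CSV with columns `age_group, weight`; bands are
#'   written `lo-hi` with a trailing `+` for the open band.
#' @return data.table with `age_group, age_lo, age_hi, weight` (weights sum
#'   to 1; `age_hi` is `Inf` for the open band).
#' @export
read_standard_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "who_world_standard_population.csv",
                        package = "elitemort", mustWork = TRUE)
  }
  w <- data.table::fread(path)
  if (!all(c("age_group", "weight") %in% names(w))) {
    stop("weights file needs columns age_group, weight")
  }
  open_band <- grepl("\\+$", w$age_group)
  lo <- as.integer(sub("[-+].*$", "", w$age_group))
  hi <- rep(Inf, nrow(w))
  hi[!open_band] <- as.integer(sub("^[0-9]+-", "", w$age_group[!open_band]))
  if (any(w$weight < 0)) stop("negative standard-population weight")
  out <- data.table::data.table(age_group = w$age_group, age_lo = lo,
                                age_hi = as.numeric(hi),
                                weight = w$weight / sum(w$weight))
  stopifnot(abs(sum(out$weight) - 1) < 1e-9)
  out
}
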