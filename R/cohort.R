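# Cohort records: loading, validation, exclusion rules, anomaly flags.
#
# A cohort table has one row per person with columns
#   id, country, sex, birth_date, death_date, office_date, status
# where status is "dead", "alive" or "unknown". A dead person should carry a
# death date; a dead person without one cannot be matched to a death year and
# is excluded (not silently treated as censored). Alive/unknown people are
# censored at the last life-table year.

COHORT_COLS <- c("id", "country", "sex", "birth_date", "death_date",
                 "office_date", "status")

#' Load a cohort file
#'
#' Reads a delimited cohort file with ISO-8601 dates. Rows that cannot be
#' parsed, or that violate date ordering (office on/before birth, death
#' before office), are quarantined with a reason rather than dropped.
#'
#' @param path CSV path with columns `id, country, sex, birth_date,
#'   death_date, office_date, status` (`death_date` may be blank;
#'   `status` defaults to "dead"/"alive" according to `death_date` if the
#'   column is absent).
#' @return list with elements `records` (data.table) and `quarantine`
#'   (data.table with a `reason` column).
#' @export
load_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  dt <- data.table::fread(path, colClasses = "character", na.strings = c("", "NA"))
  needed <- setdiff(COHORT_COLS, "status")
  missing_cols <- setdiff(needed, names(dt))
  if (length(missing_cols) > 0) {
    stop("cohort file lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"status" %in% names(dt)) {
    dt$status <- ifelse(is.na(dt$death_date), "alive", "dead")
  }
  parse_date <- function(x) as.Date(x, format = "%Y-%m-%d")
  rec <- data.table::data.table(
    id = dt$id, country = dt$country, sex = dt$sex,
    birth_date = parse_date(dt$birth_date),
    death_date = parse_date(dt$death_date),
    office_date = parse_date(dt$office_date),
    status = dt$status
  )
  reason <- rep(NA_character_, nrow(rec))
  bad_sex <- !rec$sex %in% c("male", "female")
  reason[bad_sex] <- "unparseable_sex"
  bad_status <- !rec$status %in% c("dead", "alive", "unknown")
  reason[bad_status & is.na(reason)] <- "unparseable_status"
  # dates present in the file but unparseable
  unparse <- (!is.na(dt$birth_date) & is.na(rec$birth_date)) |
    (!is.na(dt$death_date) & is.na(rec$death_date)) |
    (!is.na(dt$office_date) & is.na(rec$office_date))
  reason[unparse & is.na(reason)] <- "unparseable_date"
  no_office <- is.na(rec$office_date)
  reason[no_office & is.na(reason)] <- "missing_office_date"
  order_bad <- (!is.na(rec$birth_date) & !is.na(rec$office_date) &
                  rec$office_date <= rec$birth_date) |
    (!is.na(rec$death_date) & !is.na(rec$office_date) &
       rec$death_date < rec$office_date)
  reason[order_bad & is.na(reason)] <- "date_order_violation"
  quarantine <- rec[!is.na(reason)]
  if (nrow(quarantine) > 0) quarantine$reason <- reason[!is.na(reason)]
  else quarantine$reason <- character(0)
  list(records = rec[is.na(reason)], quarantine = quarantine)
}

#' Write a cohort table to CSV
#' @param records cohort data.table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(records, path) {
  out <- data.table::copy(data.table::as.data.table(records))
  for (col in c("birth_date", "death_date", "office_date")) {
    data.table::set(out, j = col, value = format(out[[col]], "%Y-%m-%d"))
  }
  data.table::fwrite(out, path, sep = ",", na = "")
  invisible(path)
}

#' Apply exclusion rules against a life-table surface
#'
#' A record is retained when its birth date is present, its death date is
#' present if the person is known to be dead, and its office year falls
#' within the years covered by the life-table surface (follow-up starts in
#' the first calendar year with both life-table data and office entries).
#' People without a death date who are alive or lost are retained and later
#' censored at the last life-table year, not excluded.
#'
#' @param records cohort data.table (see [load_cohort()]).
#' @param surface an annual [lifetable_surface()].
#' @return list with `records` (retained rows) and `report` (an exclusion
#'   report: counts by reason plus the retained count; reconciles to the
#'   input count).
#' @export
apply_exclusions <- function(records, surface) {
  rec <- data.table::as.data.table(records)
  n_in <- nrow(rec)
  yrs <- surface_years(surface)
  first_year <- min(yrs); last_year <- max(yrs)
  missing_dates <- is.na(rec$birth_date) |
    (rec$status == "dead" & is.na(rec$death_date))
  office_year <- year_of(rec$office_date)
  no_lifetable <- !missing_dates &
    (office_year < first_year | office_year > last_year)
  retained <- !missing_dates & !no_lifetable
  report <- data.table::data.table(
    reason = c("missing_birth_or_death_date", "no_matching_lifetable",
               "retained"),
    n = c(sum(missing_dates), sum(no_lifetable), sum(retained))
  )
  stopifnot(sum(report$n) == n_in)
  if (sum(retained) == 0) warning("no records retained after exclusions")
  list(records = rec[retained], report = report)
}

#' Flag anomalous records for manual review
#'
#' Flags (without excluding) records that died within a few months of taking
#' office, entered politics before age 21, or appear still alive beyond age
#' 102 at the reference date — the classic signatures of data errors in
#' scraped biographical records.
#'
#' @param records cohort data.table.
#' @param reference_date analysis reference date used for the
#'   "apparently still alive" check.
#' @param death_within_days threshold for death shortly after office entry
#'   (default 183 days).
#' @param min_entry_age minimum plausible entry age (default 21).
#' @param max_alive_age maximum plausible current age (default 102).
#' @return data.table of flagged records with a `flag` column; a record can
#'   appear once per flag.
#' @export
flag_anomalies <- function(records, reference_date = Sys.Date(),
                           death_within_days = 183, min_entry_age = 21,
                           max_alive_age = 102) {
  rec <- data.table::as.data.table(records)
  flags <- list()
  early_death <- !is.na(rec$death_date) &
    as.numeric(rec$death_date - rec$office_date) <= death_within_days
  if (any(early_death)) {
    flags$a <- cbind(rec[early_death], flag = "death_within_months_of_office")
  }
  entry_age <- age_at(rec$office_date, rec$birth_date)
  young <- !is.na(entry_age) & entry_age < min_entry_age
  if (any(young)) flags$b <- cbind(rec[young], flag = "entry_before_21")
  open_age <- age_at(rep(as.Date(reference_date), nrow(rec)), rec$birth_date)
  ancient <- is.na(rec$death_date) & rec$status != "dead" &
    !is.na(open_age) & open_age > max_alive_age
  if (any(ancient)) flags$c <- cbind(rec[ancient], flag = "alive_beyond_102")
  if (length(flags) == 0) {
    out <- cbind(rec[0], flag = character(0))
  } else {
    out <- data.table::rbindlist(flags)
  }
  out
}
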