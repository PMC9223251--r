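# End-to-end orchestration: read -> interpolate -> exclusions -> SMR ->
# trend (DIC table) -> direct standardization -> windows -> Gompertz ->
# gaps -> follow-up sensitivity, with CSV outputs and a provenance log.

#' Assemble a pipeline configuration
#'
#' @param lifetable_path HMD-style life-table file (with a Sex column).
#' @param cohort_path cohort CSV (see [load_cohort()]).
#' @param output_dir directory for outputs (created if needed).
#' @param country country label.
#' @param seed seed for every stochastic stage.
#' @param boot_B bootstrap replicates per window.
#' @param horizons follow-up horizons (years) for the sensitivity stage.
#' @param std_years calendar years for direct standardization (`NULL` =
#'   every 10th year of follow-up).
#' @param weights_path standard-population weights CSV (`NULL` = packaged
#'   WHO World Standard Population).
#' @param sex_filter `NULL`, "male" or "female": restrict the cohort and
#'   rerun everything on the subgroup.
#' @param windows `NULL` for consecutive 10-year windows, or a list of
#'   `c(start, end)`.
#' @param min_events event floor per window for the Gompertz stage.
#' @param trend_chains,trend_iter,trend_warmup MCMC settings for the trend.
#' @param reference_date anomaly-flag reference date.
#' @return a `run_config` list.
#' @export
run_config <- function(lifetable_path, cohort_path, output_dir,
                       country = "unknown", seed = 1, boot_B = 1000,
                       horizons = seq(10, 60, 10), std_years = NULL,
                       weights_path = NULL, sex_filter = NULL,
                       windows = NULL, min_events = 30,
                       trend_chains = 4, trend_iter = 5000,
                       trend_warmup = 1000,
                       reference_date = Sys.Date()) {
  structure(list(
    lifetable_path = lifetable_path, cohort_path = cohort_path,
    output_dir = output_dir, country = country, seed = seed,
    boot_B = boot_B, horizons = horizons, std_years = std_years,
    weights_path = weights_path, sex_filter = sex_filter,
    windows = windows, min_events = min_events,
    trend_chains = trend_chains, trend_iter = trend_iter,
    trend_warmup = trend_warmup, reference_date = reference_date
  ), class = "run_config")
}

stage <- function(name, output_dir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(output_dir, "PARTIAL_OUTPUT")
    writeLines(paste0("pipeline aborted in stage '", name, "': ",
                      conditionMessage(e)), marker)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full comparative-mortality pipeline
#'
#' Executes every stage on one country's life tables and cohort and writes
#' CSV outputs plus a JSON provenance log (config echo, seed, package
#' version, exclusion report) into the output directory. Any stage error
#' aborts with the stage name and leaves a `PARTIAL_OUTPUT` marker.
#'
#' @param config a [run_config()].
#' @return (invisibly) a list with all stage results.
#' @export
run_pipeline <- function(config) {
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!file.exists(config$lifetable_path)) {
    stop("life-table path does not exist: ", config$lifetable_path)
  }
  if (!file.exists(config$cohort_path)) {
    stop("cohort path does not exist: ", config$cohort_path)
  }

  surface <- stage("read_lifetable", out_dir, {
    s <- read_lifetable(config$lifetable_path, country = config$country)
    if (!s$annual) s <- interpolate_annual(s) else s
  })
  rep_interp <- interpolation_report(surface)
  if (!is.null(rep_interp)) {
    data.table::fwrite(rep_interp,
                       file.path(out_dir, "interpolation_report.csv"))
  }

  loaded <- stage("load_cohort", out_dir, load_cohort(config$cohort_path))
  if (!is.null(config$sex_filter)) {
    loaded$records <- loaded$records[loaded$records$sex == config$sex_filter]
  }
  excl <- stage("exclusions", out_dir,
                apply_exclusions(loaded$records, surface))
  anomalies <- stage("anomalies", out_dir,
                     flag_anomalies(excl$records,
                                    reference_date = config$reference_date))
  data.table::fwrite(excl$report, file.path(out_dir, "exclusion_report.csv"))
  if (nrow(anomalies) > 0) {
    write_cohort(anomalies, file.path(out_dir, "anomaly_flags.csv"))
  }

  last_year <- max(surface_years(surface))
  yearly <- stage("smr", out_dir,
                  smr_by_year(excl$records, surface, last_year))
  data.table::fwrite(yearly, file.path(out_dir, "smr_by_year.csv"))

  trend <- stage("trend", out_dir,
                 select_model(yearly, chains = config$trend_chains,
                              iter = config$trend_iter,
                              warmup = config$trend_warmup,
                              seed = config$seed))
  trend_out <- cbind(trend$best$curve,
                     basis = basis_label(trend$best$basis),
                     dic = trend$best$dic)
  data.table::fwrite(trend_out, file.path(out_dir, "smr_trend.csv"))
  data.table::fwrite(trend$dic_table, file.path(out_dir, "trend_dic.csv"))

  weights <- read_standard_weights(config$weights_path)
  std_years <- config$std_years
  if (is.null(std_years)) {
    with_py <- yearly$calendar_year[yearly$expected > 0]
    std_years <- with_py[with_py %% 10 == 0]
  }
  std <- stage("direct_standardization", out_dir, {
    data.table::rbindlist(lapply(std_years, function(y) {
      direct_standardized_ratio(excl$records, surface, weights, y,
                                last_year = last_year)
    }))
  })
  data.table::fwrite(std, file.path(out_dir, "direct_standardized.csv"))

  gaps <- stage("le_gaps", out_dir,
                le_gap_series(excl$records, surface,
                              windows = config$windows,
                              boot_B = config$boot_B, seed = config$seed,
                              min_events = config$min_events))
  data.table::fwrite(gaps, file.path(out_dir, "le_gaps.csv"))

  sens <- stage("followup_sensitivity", out_dir,
                followup_sensitivity(excl$records, surface,
                                     horizons = config$horizons,
                                     last_year = last_year))
  data.table::fwrite(sens, file.path(out_dir, "followup_sensitivity.csv"))

  provenance <- list(
    package_version = as.character(utils::packageVersion("elitemort")),
    r_version = R.version.string,
    seed = config$seed,
    config = config[setdiff(names(config), "reference_date")],
    reference_date = as.character(config$reference_date),
    n_input = nrow(loaded$records) + nrow(loaded$quarantine),
    n_quarantined = nrow(loaded$quarantine),
    exclusions = as.data.frame(excl$report),
    n_anomaly_flags = nrow(anomalies)
  )
  jsonlite::write_json(provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE,
                       digits = NA)
  unlink(file.path(out_dir, "PARTIAL_OUTPUT"))
  invisible(list(surface = surface, cohort = excl$records,
                 exclusion_report = excl$report, anomalies = anomalies,
                 yearly_smr = yearly, trend = trend,
                 direct_standardized = std, le_gaps = gaps,
                 sensitivity = sens))
}
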