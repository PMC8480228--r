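#' Pipeline runners
#'
#' Deterministic end-to-end stages writing tidy CSV and JSON summaries.
#' Each runner takes a configuration (a named list or the path of a YAML
#' file), validates it before writing anything, logs the full parameter set
#' into the JSON output, and removes partial outputs on error, so identical
#' configurations always produce byte-identical files.
#'
#' Recognized configuration fields (all optional unless noted):
#' `out_dir` (required), `params` (YAML file for [read_emulator_params()]),
#' `split_year`, `report_years`, `baseline_level`, `window`,
#' `spinup_years`, `table_csv`, `interventions_yaml`.
#'
#' @param config Named list or path to a YAML file.
#' @return Character vector of the files written, invisibly.
#' @name runners
NULL

load_run_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML path", call. = FALSE)
  if (is.null(config$out_dir)) stop("config$out_dir is required", call. = FALSE)
  if (!is.null(config$params) && !file.exists(config$params)) {
    stop("parameter file not found: ", config$params, call. = FALSE)
  }
  config
}

config_emulator <- function(config) {
  if (is.null(config$params)) climate_emulator() else read_emulator_params(config$params)
}

# run `writer(paths)` with cleanup of partial outputs on error
with_output_files <- function(paths, writer) {
  ok <- FALSE
  on.exit(if (!ok) unlink(paths), add = TRUE)
  writer()
  ok <- TRUE
  invisible(paths)
}

write_run_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
}

#' @rdname runners
#' @export
run_attribution <- function(config) {
  cfg <- load_run_config(config)
  em <- config_emulator(cfg)
  split_year <- if (is.null(cfg$split_year)) 2020 else cfg$split_year
  report_years <- if (is.null(cfg$report_years)) c(2050, 2100) else unlist(cfg$report_years)
  scenario <- make_mitigation_scenario()
  if (any(report_years < min(scenario$co2$years)) ||
    any(report_years > max(scenario$co2$years))) {
    stop("report years must lie within the scenario span", call. = FALSE)
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(cfg$out_dir, "attribution_series.csv")
  json_path <- file.path(cfg$out_dir, "attribution_summary.json")
  with_output_files(c(csv_path, json_path), function() {
    m_co2 <- marginal_warming(scenario$co2, split_year, em)
    m_ch4 <- marginal_warming(scenario$ch4_livestock, split_year, em)
    series <- rbind(
      cbind(as.data.frame(m_co2), component = "co2_net_marginal"),
      cbind(as.data.frame(m_ch4), component = "ch4_livestock_marginal")
    )
    utils::write.csv(series, csv_path, row.names = FALSE)
    smry <- list(
      package_version = as.character(utils::packageVersion("ch4margin")),
      parameters = as.list(coef(em)),
      split_year = split_year,
      report_years = report_years,
      marginal_co2 = stats::setNames(
        lapply(report_years, function(y) pathway_value(m_co2, y)),
        paste0("y", report_years)
      ),
      marginal_ch4_livestock = stats::setNames(
        lapply(report_years, function(y) pathway_value(m_ch4, y)),
        paste0("y", report_years)
      )
    )
    write_run_json(smry, json_path)
  })
}

#' @rdname runners
#' @export
run_budget_tradeoff <- function(config) {
  cfg <- load_run_config(config)
  em <- config_emulator(cfg)
  scenario <- make_mitigation_scenario()
  bau <- make_bau_livestock_ch4()
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(cfg$out_dir, "budget_report.json")
  csv_path <- file.path(cfg$out_dir, "adjusted_co2.csv")
  with_output_files(c(json_path, csv_path), function() {
    inv <- suppressWarnings(
      adjust_co2_for_ch4(scenario$co2, scenario$ch4_livestock, bau, em)
    )
    write_iamc_csv(inv$adjusted, csv_path)
    out <- list(
      package_version = as.character(utils::packageVersion("ch4margin")),
      parameters = as.list(coef(em)),
      scale = inv$scale, residual = inv$residual, converged = inv$converged,
      reference = unclass(inv$reference_report),
      adjusted = unclass(inv$adjusted_report),
      delta = inv$delta
    )
    write_run_json(out, json_path)
  })
}

#' @rdname runners
#' @export
run_table1 <- function(config) {
  cfg <- load_run_config(config)
  table <- if (is.null(cfg$table_csv)) read_livestock_table() else read_livestock_table(cfg$table_csv)
  ivs <- if (is.null(cfg$interventions_yaml)) read_interventions() else read_interventions(cfg$interventions_yaml)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(cfg$out_dir, "mitigation_potentials.csv")
  with_output_files(csv_path, function() {
    df <- data.frame(
      intervention = names(ivs),
      potential_mt_ch4_2050 = vapply(ivs, function(iv) {
        mitigation_potential(table, iv)
      }, numeric(1L)),
      row.names = NULL, stringsAsFactors = FALSE
    )
    utils::write.csv(df, csv_path, row.names = FALSE)
  })
}

#' @rdname runners
#' @export
run_stabilization <- function(config) {
  cfg <- load_run_config(config)
  em <- config_emulator(cfg)
  baseline <- if (is.null(cfg$baseline_level)) 115 else cfg$baseline_level
  window <- if (is.null(cfg$window)) c(2020, 2060) else unlist(cfg$window)
  spinup <- if (is.null(cfg$spinup_years)) 100 else cfg$spinup_years
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  json_path <- file.path(cfg$out_dir, "stabilization.json")
  with_output_files(json_path, function() {
    rate <- stabilizing_decline_rate(baseline, em, window, spinup)
    write_run_json(list(
      package_version = as.character(utils::packageVersion("ch4margin")),
      parameters = as.list(coef(em)),
      baseline_level = baseline, window = window, spinup_years = spinup,
      stabilizing_decline_rate_pct_per_yr = rate
    ), json_path)
  })
}
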