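#' Read emission pathways from an IAMC-style wide CSV
#'
#' Expects the columns `Model, Scenario, Region, Variable, Unit` followed by
#' year columns. Variables are mapped onto the package's gas identifiers
#' (`Emissions|CO2` -> `co2_net`, `Emissions|CH4|Livestock` ->
#' `ch4_livestock`); the `Unit` string must match the gas. Year columns must
#' form a contiguous ascending run.
#'
#' @param path Path to a CSV file.
#' @return A named list of [emissions_pathway()] objects, one per row, named
#'   `<Scenario>.<gas>`.
#' @export
read_iamc_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta_cols <- c("Model", "Scenario", "Region", "Variable", "Unit")
  if (!all(meta_cols %in% names(df))) {
    stop("IAMC CSV must have columns ", paste(meta_cols, collapse = ", "),
      call. = FALSE
    )
  }
  year_cols <- setdiff(names(df), meta_cols)
  years <- suppressWarnings(as.integer(year_cols))
  if (length(years) == 0L || anyNA(years)) {
    stop("IAMC CSV has no valid year columns", call. = FALSE)
  }
  if (any(diff(years) != 1L)) {
    stop("IAMC year columns must be contiguous", call. = FALSE)
  }
  var_map <- c(
    "Emissions|CO2" = "co2_net",
    "Emissions|CH4|Livestock" = "ch4_livestock"
  )
  out <- list()
  for (i in seq_len(nrow(df))) {
    var <- df$Variable[i]
    gas <- unname(var_map[var])
    if (is.na(gas)) stop("unknown IAMC variable: ", var, call. = FALSE)
    if (!identical(df$Unit[i], gas_unit(gas))) {
      stop(
        "unit mismatch for ", var, ": expected \"", gas_unit(gas),
        "\", found \"", df$Unit[i], "\"",
        call. = FALSE
      )
    }
    values <- as.numeric(df[i, year_cols])
    p <- emissions_pathway(gas, years, values, label = df$Scenario[i])
    out[[paste(df$Scenario[i], gas, sep = ".")]] <- p
  }
  out
}

#' Write emission pathways to an IAMC-style wide CSV
#'
#' Inverse of [read_iamc_csv()]: a write-then-read round trip reproduces the
#' pathway values to full double precision. All pathways must share the same
#' year axis.
#'
#' @param pathways A single [emissions_pathway()] or a list of them.
#' @param path Output CSV path.
#' @param model,region Metadata strings for the corresponding columns.
#' @return `path`, invisibly.
#' @export
write_iamc_csv <- function(pathways, path, model = "ch4margin", region = "World") {
  if (inherits(pathways, "emissions_pathway")) pathways <- list(pathways)
  stopifnot(all(vapply(pathways, inherits, logical(1L), "emissions_pathway")))
  years <- pathways[[1L]]$years
  for (p in pathways) {
    if (!identical(p$years, years)) {
      stop("all pathways must share the same year axis", call. = FALSE)
    }
  }
  rows <- lapply(pathways, function(p) {
    row <- data.frame(
      Model = model,
      Scenario = if (nzchar(p$label)) p$label else "unnamed",
      Region = region,
      Variable = gas_variable(p$gas),
      Unit = p$unit,
      stringsAsFactors = FALSE,
      check.names = FALSE
    )
    vals <- as.data.frame(as.list(p$values), check.names = FALSE)
    names(vals) <- as.character(p$years)
    cbind(row, vals)
  })
  df <- do.call(rbind, rows)
  # full precision so the round trip is exact
  num_cols <- as.character(years)
  df[num_cols] <- lapply(df[num_cols], function(v) sprintf("%.17g", v))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
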