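#' Marginal warming from emissions after a split year
#'
#' Marginal warming is the warming an additional set of emissions causes,
#' relative to their absence, all else equal. This function computes
#' `warming(pathway) - warming(pathway zeroed after split_year)`; in the
#' default linearized forcing mode this equals the warming of the
#' future-only emissions, and it is exactly zero at and before the split
#' year.
#'
#' @param pathway An [emissions_pathway()].
#' @param split_year Last year whose emissions count as past (default 2020);
#'   zeroing begins the following year. Must lie on the pathway axis.
#' @param emulator A [climate_emulator()].
#' @return A `temperature_series`.
#' @examples
#' sc <- make_mitigation_scenario()
#' m <- marginal_warming(sc$co2, 2020)
#' pathway_value(m, 2050) # about 0.25 degC
#' @export
marginal_warming <- function(pathway, split_year = 2020,
                             emulator = climate_emulator()) {
  stopifnot(inherits(pathway, "emissions_pathway"))
  if (!split_year %in% pathway$years) {
    stop("split year ", split_year, " is outside the pathway axis", call. = FALSE)
  }
  full <- warming_from_emissions(pathway, emulator)
  past <- warming_from_emissions(zero_after(pathway, split_year), emulator)
  out <- series_minus(full, past)
  out$label <- paste0(pathway$label, " marginal (split ", split_year, ")")
  out
}

#' Legacy warming from historical emissions
#'
#' Warming attributable to emissions up to the end of the historical series,
#' with zero emissions afterwards. For CH4 the legacy signal decays towards
#' zero within decades (only the thermal tail remains); for CO2 it persists
#' because a large fraction of the concentration anomaly does.
#'
#' @param history An [emissions_pathway()], typically from
#'   [historical_backdrop()].
#' @param emulator A [climate_emulator()].
#' @param through_year Extend the (zero-emission) axis to this year
#'   (default 2100).
#' @return A `temperature_series` carrying attribute `stylized` from the
#'   input so fixture-dependent results stay flagged.
#' @export
legacy_warming <- function(history, emulator = climate_emulator(),
                           through_year = 2100) {
  stopifnot(inherits(history, "emissions_pathway"))
  last <- max(history$years)
  if (through_year > last) {
    ext_years <- (last + 1):through_year
    history <- emissions_pathway(
      history$gas, c(history$years, ext_years),
      c(history$values, rep(0, length(ext_years))),
      label = history$label
    )
  }
  out <- warming_from_emissions(history, emulator)
  out$label <- paste0(out$label, " legacy")
  attr(out, "stylized") <- isTRUE(attr(history, "stylized"))
  out
}

#' Legacy/marginal warming decomposition
#'
#' Splits the warming of a full (historical + projected) emission series
#' into legacy warming from emissions up to the split year and marginal
#' warming from emissions after it. In linearized mode the decomposition is
#' additive to machine precision: total = legacy + marginal at every year.
#'
#' @param history Historical [emissions_pathway()] ending at `split_year`
#'   (e.g. [historical_backdrop()]).
#' @param future Projection [emissions_pathway()] whose axis covers
#'   `split_year`; values after `split_year` are appended to the history.
#' @param split_year Split between past and future (default 2020).
#' @param emulator A [climate_emulator()].
#' @param report_years Years summarized in the printout (default 2050,
#'   2100).
#' @return An object of class `warming_attribution` with elements
#'   `component` (gas), `split_year`, `total`, `legacy` and `marginal`
#'   temperature series, and `summary` (data frame of report-year values).
#' @export
attribute_warming <- function(history, future, split_year = 2020,
                              emulator = climate_emulator(),
                              report_years = c(2050, 2100)) {
  stopifnot(
    inherits(history, "emissions_pathway"),
    inherits(future, "emissions_pathway"),
    identical(history$gas, future$gas)
  )
  if (max(history$years) != split_year) {
    stop("history must end at the split year", call. = FALSE)
  }
  fut_years <- future$years[future$years > split_year]
  if (length(fut_years) == 0L) stop("future pathway ends at the split year", call. = FALSE)
  combined <- emissions_pathway(
    history$gas,
    c(history$years, fut_years),
    c(history$values, future$values[future$years > split_year]),
    label = paste0(future$label, " incl. history")
  )
  total <- warming_from_emissions(combined, emulator)
  legacy <- warming_from_emissions(zero_after(combined, split_year), emulator)
  marginal <- series_minus(total, legacy)
  marginal$label <- paste0(future$label, " marginal")
  legacy$label <- paste0(future$label, " legacy")
  smry <- data.frame(
    year = report_years,
    total = vapply(report_years, function(y) pathway_value(total, y), numeric(1L)),
    legacy = vapply(report_years, function(y) pathway_value(legacy, y), numeric(1L)),
    marginal = vapply(report_years, function(y) pathway_value(marginal, y), numeric(1L))
  )
  structure(
    list(
      component = future$gas, split_year = split_year,
      total = total, legacy = legacy, marginal = marginal,
      summary = smry,
      stylized_history = isTRUE(attr(history, "stylized"))
    ),
    class = "warming_attribution"
  )
}

#' @export
print.warming_attribution <- function(x, ...) {
  cat(sprintf(
    "<warming_attribution> %s, split %d%s\n", x$component, x$split_year,
    if (x$stylized_history) " (legacy/total use a stylized history)" else ""
  ))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.warming_attribution <- function(x, ...) {
  yl <- range(x$total$values, x$legacy$values, x$marginal$values)
  graphics::plot(x$total$years, x$total$values,
    type = "l", lwd = 2,
    xlab = "year", ylab = "warming anomaly [degC]",
    main = paste(x$component, "warming decomposition"), ylim = yl, ...
  )
  graphics::lines(x$legacy$years, x$legacy$values, lty = 2)
  graphics::lines(x$marginal$years, x$marginal$values, lty = 3)
  graphics::legend("topleft",
    legend = c("total", "legacy", "marginal"),
    lty = 1:3, lwd = c(2, 1, 1), bty = "n"
  )
  invisible(x)
}

#' Warming share from a product of fractional shares
#'
#' Approximates a source's share of anthropogenic warming as the product of
#' its share of total radiative forcing and its share within the source
#' category, reported as a percentage. (For example, methane contributing
#' just over 40\% of forcing with livestock contributing roughly 30\% of
#' methane gives roughly 12\% of warming to date.)
#'
#' @param forcing_share Fraction in `[0, 1]`.
#' @param source_share Fraction in `[0, 1]`.
#' @return Percentage (0-100).
#' @examples
#' warming_share_product(0.40, 0.30) # 12
#' @export
warming_share_product <- function(forcing_share, source_share) {
  if (forcing_share < 0 || forcing_share > 1 || source_share < 0 || source_share > 1) {
    stop("shares must lie in [0, 1]", call. = FALSE)
  }
  100 * forcing_share * source_share
}
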