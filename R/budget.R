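#' Net-zero year of a pathway
#'
#' First downward zero-crossing of the annual series, linearly interpolated
#' between the bracketing years. A year with value exactly zero (preceded by
#' a positive value) is itself the net-zero year. If the pathway never
#' crosses zero the result is `NA_real_` ("never"), not an error.
#'
#' @param pathway An [emissions_pathway()].
#' @return Fractional calendar year, or `NA_real_` if there is no crossing.
#' @examples
#' p <- emissions_pathway("co2_net", 2040:2041, c(2, -2))
#' net_zero_year(p) # 2040.5
#' @export
net_zero_year <- function(pathway) {
  stopifnot(inherits(pathway, "emissions_pathway"))
  v <- pathway$values
  y <- pathway$years
  for (i in seq_len(length(v) - 1L)) {
    if (v[i] > 0 && v[i + 1L] <= 0) {
      return(y[i] + v[i] / (v[i] - v[i + 1L]))
    }
  }
  NA_real_
}

#' Geometric annual reduction rate over a window
#'
#' The constant annual rate `r` such that the value at `y1` equals the value
#' at `y0` scaled by `(1 - r)^(y1 - y0)`, i.e.
#' `100 * (1 - (v1/v0)^(1/(y1 - y0)))` percent per year. Both endpoint
#' values must be strictly positive.
#'
#' @param pathway An [emissions_pathway()].
#' @param y0,y1 Window endpoints (years on the pathway axis, `y1 > y0`).
#' @return Rate in percent per year (positive for a decline).
#' @examples
#' p <- emissions_pathway("co2_net", 2020:2030, seq(100, 50, length.out = 11))
#' annual_reduction_rate(p, 2020, 2030)
#' @export
annual_reduction_rate <- function(pathway, y0, y1) {
  stopifnot(inherits(pathway, "emissions_pathway"), y1 > y0)
  v0 <- pathway_value(pathway, y0)
  v1 <- pathway_value(pathway, y1)
  if (v0 <= 0 || v1 <= 0) {
    stop("endpoint values must be strictly positive for a geometric rate",
      call. = FALSE
    )
  }
  100 * (1 - (v1 / v0)^(1 / (y1 - y0)))
}

#' Cumulative net CO2 from a start year to net-zero
#'
#' Trapezoidal integral of the annual pathway from `start_year` to its
#' (fractional) net-zero year, treating the series as piecewise linear
#' between year points. If the pathway never reaches net-zero the result is
#' `NA_real_`.
#'
#' @param pathway An [emissions_pathway()] (Gt CO2/yr).
#' @param start_year First year of the integral; must be on the axis.
#' @return Cumulative emissions in Gt CO2, or `NA_real_`.
#' @export
cumulative_to_net_zero <- function(pathway, start_year) {
  stopifnot(inherits(pathway, "emissions_pathway"))
  if (!start_year %in% pathway$years) {
    stop("start year ", start_year, " is not on the pathway axis", call. = FALSE)
  }
  nz <- net_zero_year(pathway)
  if (is.na(nz)) {
    return(NA_real_)
  }
  y <- pathway$years
  v <- pathway$values
  i0 <- match(start_year, y)
  last_full <- floor(nz)
  i1 <- match(last_full, y)
  total <- 0
  if (i1 > i0) {
    total <- sum((v[i0:(i1 - 1L)] + v[(i0 + 1L):i1]) / 2)
  }
  # partial trapezoid from the last integer year to the fractional crossing
  frac <- nz - last_full
  if (frac > 0) {
    total <- total + v[i1] * frac / 2
  }
  total
}

#' Fraction of a reference carbon budget
#'
#' @param delta_gt Budget change in Gt CO2.
#' @param reference_budget_gt Reference budget in Gt CO2 (> 0).
#' @return Percentage `100 * delta / reference`.
#' @examples
#' budget_fraction(136, 1170) # about 11.6
#' @export
budget_fraction <- function(delta_gt, reference_budget_gt) {
  if (reference_budget_gt <= 0) {
    stop("reference budget must be > 0", call. = FALSE)
  }
  100 * delta_gt / reference_budget_gt
}

#' Budget diagnostics for a net CO2 pathway
#'
#' @param pathway An [emissions_pathway()] (Gt CO2/yr).
#' @param start_year First year of the cumulative budget (default 2018).
#' @param rate_window Two years over which the geometric reduction rate is
#'   evaluated (default 2020-2030).
#' @return An object of class `budget_report` with elements `label`,
#'   `net_zero_year`, `reduction_rate` (%/yr), `cumulative` (Gt CO2),
#'   `start_year` and `rate_window`.
#' @export
budget_report <- function(pathway, start_year = 2018,
                          rate_window = c(2020, 2030)) {
  structure(
    list(
      label = pathway$label,
      net_zero_year = net_zero_year(pathway),
      reduction_rate = annual_reduction_rate(pathway, rate_window[1L], rate_window[2L]),
      cumulative = cumulative_to_net_zero(pathway, start_year),
      start_year = start_year,
      rate_window = rate_window
    ),
    class = "budget_report"
  )
}

#' @export
print.budget_report <- function(x, ...) {
  cat(sprintf("<budget_report> %s\n", x$label))
  cat(sprintf(
    "  net-zero year: %s\n",
    if (is.na(x$net_zero_year)) "never" else sprintf("%.1f", x$net_zero_year)
  ))
  cat(sprintf(
    "  reduction rate %d-%d: %.2f %%/yr\n",
    x$rate_window[1L], x$rate_window[2L], x$reduction_rate
  ))
  cat(sprintf(
    "  cumulative net CO2 %d -> net-zero: %s Gt\n", x$start_year,
    if (is.na(x$cumulative)) "undefined" else sprintf("%.1f", x$cumulative)
  ))
  invisible(x)
}

#' Difference between two budget reports
#'
#' Element-wise `b - a` deltas; antisymmetric under swapping the arguments.
#'
#' @param a,b [budget_report()] objects.
#' @return A list with `net_zero_year`, `reduction_rate` and `cumulative`
#'   deltas.
#' @export
budget_report_delta <- function(a, b) {
  stopifnot(inherits(a, "budget_report"), inherits(b, "budget_report"))
  list(
    net_zero_year = b$net_zero_year - a$net_zero_year,
    reduction_rate = b$reduction_rate - a$reduction_rate,
    cumulative = b$cumulative - a$cumulative
  )
}

# one-parameter CO2 pathway family used by the inversion: scale the decline
# increments over (split, ramp_end], then rejoin the reference shape with a
# linearly tapering offset pinned to the reference level in 2100
co2_family_member <- function(co2_ref, scale, split = 2020, ramp_end = 2035) {
  y <- co2_ref$years
  v <- co2_ref$values
  out <- v
  ramp <- y > split & y <= ramp_end
  incr <- diff(v[y >= split & y <= ramp_end])
  i0 <- match(split, y)
  out[ramp] <- v[i0] + cumsum(scale * incr)
  offset_end <- out[match(ramp_end, y)] - v[match(ramp_end, y)]
  tail_idx <- y > ramp_end
  taper <- (2100 - y[tail_idx]) / (2100 - ramp_end)
  out[tail_idx] <- v[tail_idx] + offset_end * pmax(taper, 0)
  emissions_pathway("co2_net", y, out,
    label = sprintf("%s (adjusted, scale %.4f)", co2_ref$label, scale)
  )
}

#' Temperature-matched CO2 adjustment for an alternative CH4 pathway
#'
#' Finds the net CO2 pathway that compensates the extra warming of an
#' alternative (higher) livestock CH4 pathway so that the combined CO2+CH4
#' warming trajectory stays virtually identical to the reference scenario's.
#' The adjusted pathway comes from a one-parameter family: the reference
#' decline increments over `split`-`ramp_end` are multiplied by a scalar,
#' after which the pathway rejoins the reference shape via a linearly
#' tapering offset pinned to the same 2100 floor. The scalar is found by a
#' bracketed root solve that balances the largest warm and cool deviations
#' over `split`-2100 (the minimax choice for a monotone family), and the
#' achieved residual is compared with `tolerance`.
#'
#' @param co2_ref Reference net CO2 [emissions_pathway()].
#' @param ch4_ref Reference (mitigated) CH4 [emissions_pathway()].
#' @param ch4_alt Alternative CH4 pathway; must be >= the reference at every
#'   year after `split`.
#' @param emulator A [climate_emulator()].
#' @param split First year of the matching window (default 2020).
#' @param ramp_end Last year whose decline increments are rescaled
#'   (default 2035).
#' @param bracket Search bracket for the scale parameter (default
#'   `c(0.5, 3)`).
#' @param tolerance Acceptable maximum absolute combined-warming difference
#'   in deg C (default 0.01).
#' @param start_year,rate_window Passed to [budget_report()].
#' @return An object of class `budget_tradeoff`: the adjusted pathway,
#'   `scale`, `residual` (max |deltaT| over the window), `converged`
#'   (residual <= tolerance), reference and adjusted [budget_report()]s and
#'   their `delta`.
#' @examples
#' \donttest{
#' sc <- make_mitigation_scenario()
#' bau <- make_bau_livestock_ch4()
#' inv <- adjust_co2_for_ch4(sc$co2, sc$ch4_livestock, bau)
#' inv$delta$cumulative # negative: smaller remaining budget
#' }
#' @export
adjust_co2_for_ch4 <- function(co2_ref, ch4_ref, ch4_alt,
                               emulator = climate_emulator(),
                               split = 2020, ramp_end = 2035,
                               bracket = c(0.5, 3), tolerance = 0.01,
                               start_year = 2018, rate_window = c(2020, 2030)) {
  stopifnot(
    inherits(co2_ref, "emissions_pathway"),
    inherits(ch4_ref, "emissions_pathway"),
    inherits(ch4_alt, "emissions_pathway"),
    identical(ch4_ref$years, ch4_alt$years),
    identical(co2_ref$years, ch4_ref$years),
    tolerance > 0
  )
  post <- ch4_ref$years >= split
  if (any(ch4_alt$values[post] < ch4_ref$values[post] - 1e-9)) {
    stop("alternative CH4 must be >= the reference at all years >= ", split,
      call. = FALSE
    )
  }
  window <- co2_ref$years >= split
  d_ch4 <- series_minus(
    warming_from_emissions(ch4_alt, emulator),
    warming_from_emissions(ch4_ref, emulator)
  )
  t_co2_ref <- warming_from_emissions(co2_ref, emulator)
  combined_diff <- function(scale) {
    adj <- co2_family_member(co2_ref, scale, split, ramp_end)
    d_co2 <- series_minus(warming_from_emissions(adj, emulator), t_co2_ref)
    (d_co2$values + d_ch4$values)[window]
  }
  balance <- function(scale) {
    d <- combined_diff(scale)
    max(d) + min(d)
  }
  b_lo <- balance(bracket[1L])
  b_hi <- balance(bracket[2L])
  if (sign(b_lo) != sign(b_hi)) {
    scale <- stats::uniroot(balance, bracket, tol = 1e-4)$root
  } else {
    # family cannot balance the deviations; report the better endpoint
    scale <- bracket[which.min(c(
      max(abs(combined_diff(bracket[1L]))),
      max(abs(combined_diff(bracket[2L])))
    ))]
  }
  residual <- max(abs(combined_diff(scale)))
  converged <- residual <= tolerance
  if (!converged) {
    warning(sprintf(
      "inversion residual %.4f degC exceeds tolerance %.4f degC",
      residual, tolerance
    ), call. = FALSE)
  }
  adjusted <- co2_family_member(co2_ref, scale, split, ramp_end)
  ref_report <- budget_report(co2_ref, start_year, rate_window)
  adj_report <- budget_report(adjusted, start_year, rate_window)
  structure(
    list(
      adjusted = adjusted, scale = scale,
      residual = residual, converged = converged, tolerance = tolerance,
      reference_report = ref_report, adjusted_report = adj_report,
      delta = budget_report_delta(ref_report, adj_report)
    ),
    class = "budget_tradeoff"
  )
}

#' @export
print.budget_tradeoff <- function(x, ...) {
  cat(sprintf(
    "<budget_tradeoff> scale %.4f, residual %.4f degC (%s)\n",
    x$scale, x$residual,
    if (x$converged) "within tolerance" else "NOT within tolerance"
  ))
  print(x$reference_report)
  print(x$adjusted_report)
  cat(sprintf(
    "  deltas: net-zero %+.1f yr, rate %+.2f pp/yr, budget %+.1f Gt\n",
    x$delta$net_zero_year, x$delta$reduction_rate, x$delta$cumulative
  ))
  invisible(x)
}

#' @export
plot.budget_tradeoff <- function(x, ...) {
  ref <- x$reference_report
  graphics::plot(x$adjusted$years, x$adjusted$values,
    type = "l", lty = 2,
    xlab = "year", ylab = "net CO2 [Gt/yr]", main = "temperature-matched CO2 pathways", ...
  )
  graphics::abline(h = 0, col = "grey")
  invisible(x)
}

#' CH4 decline rate that stabilizes CH4-induced warming
#'
#' Finds the constant exponential decline rate of CH4 emissions such that
#' the CH4-induced warming at the end of an evaluation window equals the
#' warming at its start. Emissions are held constant at `baseline_level`
#' during a spin-up period, then decline at rate `r` from the window start;
#' the root of `T(end) - T(start)` in `r` is found by bisection. A positive
#' rate is needed because the slow thermal mode keeps warming even under
#' constant forcing; with near-instant thermal equilibration the rate tends
#' to zero.
#'
#' @param baseline_level Constant CH4 emissions during spin-up (Mt/yr, > 0).
#' @param emulator A [climate_emulator()].
#' @param window Start and end year of the stabilization window (default
#'   `c(2020, 2060)`; at least 40 years).
#' @param spinup_years Length of the constant-emission spin-up before the
#'   window (default 100).
#' @param upper Upper bisection bound on the rate (fraction/yr, default
#'   0.02).
#' @return Decline rate in percent per year.
#' @examples
#' \donttest{
#' stabilizing_decline_rate(115) # about 0.2-0.3 %/yr
#' }
#' @export
stabilizing_decline_rate <- function(baseline_level,
                                     emulator = climate_emulator(),
                                     window = c(2020, 2060),
                                     spinup_years = 100,
                                     upper = 0.02) {
  stopifnot(baseline_level > 0)
  if (diff(window) < 40) stop("window must span at least 40 years", call. = FALSE)
  years <- (window[1L] - spinup_years):window[2L]
  drift <- function(r) {
    decline <- (1 - r)^(pmax(years - window[1L], 0))
    p <- emissions_pathway("ch4_livestock", years, baseline_level * decline)
    tw <- warming_from_emissions(p, emulator)
    pathway_value(tw, window[2L]) - pathway_value(tw, window[1L])
  }
  f_lo <- drift(0)
  f_hi <- drift(upper)
  if (f_lo <= 0) {
    return(0)
  } # already stable (or cooling) under constant emissions
  if (f_hi > 0) {
    stop(sprintf(
      "no sign change in bracket [0, %.3f]: drift at upper bound %.4g degC",
      upper, f_hi
    ), call. = FALSE)
  }
  r <- stats::uniroot(drift, c(0, upper), tol = 1e-7)$root
  100 * r
}
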