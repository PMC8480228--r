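#' Annual emissions pathway
#'
#' Container for an annual global emission series for one gas. Years must be
#' contiguous calendar years; an emission value for year `t` is the total for
#' calendar year `t`. Net CO2 may be negative (net removal); livestock CH4
#' must be nonnegative.
#'
#' @param gas One of `"co2_net"` (units Gt CO2/yr) or `"ch4_livestock"`
#'   (units Mt CH4/yr).
#' @param years Integer vector of contiguous, ascending calendar years.
#' @param values Numeric vector of annual emissions, same length as `years`.
#' @param label Free-text label describing the pathway.
#' @return An object of class `emissions_pathway`: a list with elements
#'   `gas`, `years`, `values`, `unit` and `label`.
#' @examples
#' p <- emissions_pathway("co2_net", 2020:2022, c(35, 34, 33), "example")
#' pathway_value(p, 2021)
#' @export
emissions_pathway <- function(gas, years, values, label = "") {
  gas <- match.arg(gas, c("co2_net", "ch4_livestock"))
  years <- as.integer(years)
  values <- as.numeric(values)
  if (length(years) != length(values)) {
    stop("`years` and `values` must have the same length", call. = FALSE)
  }
  if (length(years) == 0L) stop("pathway must contain at least one year", call. = FALSE)
  if (length(years) > 1L && any(diff(years) != 1L)) {
    stop("`years` must be contiguous with step 1", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("`values` must be finite", call. = FALSE)
  if (gas == "ch4_livestock" && any(values < 0)) {
    stop("livestock CH4 emissions must be >= 0", call. = FALSE)
  }
  structure(
    list(
      gas = gas,
      years = years,
      values = values,
      unit = gas_unit(gas),
      label = as.character(label)[1L]
    ),
    class = "emissions_pathway"
  )
}

gas_unit <- function(gas) {
  switch(gas,
    co2_net = "Gt CO2/yr",
    ch4_livestock = "Mt CH4/yr",
    stop("unknown gas: ", gas, call. = FALSE)
  )
}

gas_variable <- function(gas) {
  switch(gas,
    co2_net = "Emissions|CO2",
    ch4_livestock = "Emissions|CH4|Livestock",
    stop("unknown gas: ", gas, call. = FALSE)
  )
}

#' @export
print.emissions_pathway <- function(x, ...) {
  cat(sprintf(
    "<emissions_pathway> %s [%s], %d-%d%s\n",
    x$gas, x$unit, min(x$years), max(x$years),
    if (nzchar(x$label)) paste0(" \"", x$label, "\"") else ""
  ))
  cat(sprintf(
    "  first/last values: %.3f -> %.3f\n",
    x$values[1L], x$values[length(x$values)]
  ))
  invisible(x)
}

#' @export
as.data.frame.emissions_pathway <- function(x, ...) {
  data.frame(
    year = x$years, value = x$values, gas = x$gas, unit = x$unit,
    stringsAsFactors = FALSE
  )
}

#' Look up a pathway (or series) value at a year
#'
#' @param x An `emissions_pathway` or `annual_series`.
#' @param year Calendar year; must be on the axis of `x`.
#' @return The value at `year`.
#' @export
pathway_value <- function(x, year) {
  i <- match(as.integer(year), x$years)
  if (anyNA(i)) stop("year ", year[which(is.na(i))[1L]], " not on pathway axis", call. = FALSE)
  x$values[i]
}

#' Zero a pathway after a split year
#'
#' Returns a copy of the pathway with all values strictly after `split_year`
#' set to zero; used to separate legacy from marginal emissions.
#'
#' @param x An `emissions_pathway`.
#' @param split_year Last year whose emissions are retained.
#' @return An `emissions_pathway`.
#' @export
zero_after <- function(x, split_year) {
  stopifnot(inherits(x, "emissions_pathway"))
  x$values[x$years > split_year] <- 0
  x$label <- paste0(x$label, " (zeroed after ", split_year, ")")
  x
}

#' Restrict a pathway or series to a year window
#'
#' @param x An `emissions_pathway` or `annual_series`.
#' @param y0,y1 First and last year to keep.
#' @return Object of the same class on the restricted axis.
#' @export
window_years <- function(x, y0, y1) {
  keep <- x$years >= y0 & x$years <= y1
  if (!any(keep)) stop("window [", y0, ", ", y1, "] is outside the year axis", call. = FALSE)
  x$years <- x$years[keep]
  x$values <- x$values[keep]
  x
}

#' Scenario anchors
#'
#' A sparse set of (year, value) anchor points plus an interpolation rule,
#' from which an annual pathway is built. `"monotone"` uses the
#' Fritsch-Carlson shape-preserving monotone cubic interpolant
#' ([stats::splinefun()] with `method = "monoH.FC"`), which never overshoots
#' the local anchor range; `"linear"` is piecewise linear. Outside the anchor
#' span values are held constant at the nearest anchor.
#'
#' @param years Strictly increasing anchor years, within 1850-2100.
#' @param values Anchor values.
#' @param method `"monotone"` (default) or `"linear"`.
#' @return An object of class `scenario_anchors`.
#' @export
scenario_anchors <- function(years, values, method = c("monotone", "linear")) {
  method <- match.arg(method)
  years <- as.numeric(years)
  values <- as.numeric(values)
  if (length(years) < 1L) stop("need at least one anchor", call. = FALSE)
  if (length(years) != length(values)) stop("anchor years/values length mismatch", call. = FALSE)
  if (length(years) > 1L && any(diff(years) <= 0)) {
    stop("anchor years must be strictly increasing", call. = FALSE)
  }
  if (any(years < 1850 | years > 2100)) {
    stop("anchor years must lie within [1850, 2100]", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("anchor values must be finite", call. = FALSE)
  structure(list(years = years, values = values, method = method),
    class = "scenario_anchors"
  )
}

#' Build an annual pathway from anchors
#'
#' Interpolates the anchors onto an annual axis. The pathway passes exactly
#' through every anchor whose year is integral; extrapolation beyond the
#' anchor span holds the boundary anchor value constant.
#'
#' @param anchors A [scenario_anchors()] object.
#' @param gas Gas identifier as in [emissions_pathway()].
#' @param years Output years; default spans the anchor years.
#' @param label Pathway label.
#' @return An `emissions_pathway`.
#' @examples
#' a <- scenario_anchors(c(2020, 2030), c(0, 10), method = "linear")
#' build_pathway_from_anchors(a, "co2_net")
#' @export
build_pathway_from_anchors <- function(anchors, gas,
                                       years = NULL, label = "") {
  stopifnot(inherits(anchors, "scenario_anchors"))
  if (is.null(years)) {
    years <- seq.int(floor(min(anchors$years)), ceiling(max(anchors$years)))
  }
  values <- interpolate_anchors(anchors, years)
  emissions_pathway(gas, years, values, label)
}

interpolate_anchors <- function(anchors, at) {
  ay <- anchors$years
  av <- anchors$values
  if (length(ay) == 1L) {
    return(rep(av, length(at)))
  }
  inside <- at >= min(ay) & at <= max(ay)
  out <- numeric(length(at))
  if (anchors$method == "linear") {
    out[inside] <- stats::approx(ay, av, xout = at[inside])$y
  } else {
    # apply the monotone cubic per maximal monotone run of anchors, so the
    # interpolant never overshoots the local anchor range even at turning
    # points (slopes at local extrema come one-sided from each run)
    runs <- monotone_runs(av)
    vals <- at[inside]
    res <- numeric(length(vals))
    for (r in runs) {
      sel <- vals >= ay[r[1L]] & vals <= ay[r[length(r)]]
      if (!any(sel)) next
      res[sel] <- if (length(r) == 1L) {
        av[r]
      } else {
        stats::splinefun(ay[r], av[r], method = "monoH.FC")(vals[sel])
      }
    }
    out[inside] <- res
  }
  out[at < min(ay)] <- av[1L]
  out[at > max(ay)] <- av[length(av)]
  out
}

# indices of maximal monotone (non-increasing or non-decreasing) runs
monotone_runs <- function(v) {
  n <- length(v)
  if (n <= 2L) {
    return(list(seq_len(n)))
  }
  runs <- list()
  start <- 1L
  dir <- 0
  for (i in 2:n) {
    step <- sign(v[i] - v[i - 1L])
    if (dir == 0) {
      dir <- step
    } else if (step != 0 && step != dir) {
      runs[[length(runs) + 1L]] <- start:(i - 1L)
      start <- i - 1L
      dir <- step
    }
  }
  runs[[length(runs) + 1L]] <- start:n
  runs
}

#' Annual series (concentration, forcing or temperature anomaly)
#'
#' Internal constructor for derived series sharing the driving pathway's
#' year axis. Values are anomalies relative to the pathway start.
#'
#' @param years Contiguous years.
#' @param values Numeric values.
#' @param kind One of `"concentration"`, `"forcing"`, `"temperature"`.
#' @param unit Unit string.
#' @param label Label.
#' @return An object of class `c("<kind>_series", "annual_series")`.
#' @export
annual_series <- function(years, values, kind, unit, label = "") {
  stopifnot(length(years) == length(values))
  structure(
    list(
      years = as.integer(years), values = as.numeric(values),
      kind = kind, unit = unit, label = as.character(label)[1L]
    ),
    class = c(paste0(kind, "_series"), "annual_series")
  )
}

#' @export
print.annual_series <- function(x, ...) {
  cat(sprintf(
    "<%s_series> [%s], %d-%d%s\n", x$kind, x$unit,
    min(x$years), max(x$years),
    if (nzchar(x$label)) paste0(" \"", x$label, "\"") else ""
  ))
  idx <- unique(pmin(length(x$years), c(1L, length(x$years))))
  for (i in idx) cat(sprintf("  %d: %.4f\n", x$years[i], x$values[i]))
  invisible(x)
}

#' @export
as.data.frame.annual_series <- function(x, ...) {
  data.frame(
    year = x$years, value = x$values, variable = x$kind, unit = x$unit,
    stringsAsFactors = FALSE
  )
}

#' @export
plot.annual_series <- function(x, ...) {
  graphics::plot(x$years, x$values,
    type = "l", xlab = "year",
    ylab = paste0(x$kind, " [", x$unit, "]"), main = x$label, ...
  )
  invisible(x)
}

series_minus <- function(a, b) {
  stopifnot(identical(a$years, b$years), identical(a$kind, b$kind))
  annual_series(a$years, a$values - b$values, a$kind, a$unit,
    label = paste(a$label, "-", b$label)
  )
}

series_plus <- function(a, b) {
  stopifnot(identical(a$years, b$years), identical(a$kind, b$kind))
  annual_series(a$years, a$values + b$values, a$kind, a$unit,
    label = paste(a$label, "+", b$label)
  )
}
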