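#' Scenario generator configuration
#'
#' Defaults encode the stylized 1.5 degree-consistent mitigation pathway and
#' the business-as-usual (BAU) livestock CH4 projection used throughout the
#' package: net CO2 starts at 35 Gt/yr in 2020, declines geometrically at
#' 4.9\%/yr to 2030, reaches net-zero in 2055 and falls to -10 Gt/yr by 2100,
#' with the 2030-2055 segment calibrated so that cumulative net CO2 from 2018
#' to net-zero is 580 Gt; livestock CH4 falls 38\% between 2010 and 2050 to
#' 70 Mt/yr and declines further to 55 Mt/yr by 2100; the BAU CH4 pathway
#' instead grows 30\% above its 2010 level by 2050 and is held constant
#' afterwards. All anchor levels are configurable; the generators are fully
#' deterministic.
#'
#' @param years Scenario year axis (default 2000-2100).
#' @param co2_2000,co2_2010,co2_2020 Net CO2 levels (Gt/yr) pinning the
#'   pre-projection segment.
#' @param co2_decline Geometric annual decline rate of net CO2 over
#'   2020-2030 (fraction, default 0.049).
#' @param co2_net_zero Year net CO2 reaches zero (default 2055).
#' @param co2_floor_2100 Net CO2 level in 2100 (Gt/yr, default -10).
#' @param co2_budget Cumulative net CO2 target (Gt) from `budget_start` to
#'   the net-zero year (default 580).
#' @param budget_start First year of the cumulative budget (default 2018).
#' @param co2_calibration_year Year of the free anchor between 2030 and the
#'   net-zero year whose level is solved to hit `co2_budget` (default 2042).
#' @param ch4_2050 Mitigated livestock CH4 in 2050 (Mt/yr, default 70).
#' @param ch4_drop_2050 Fractional drop of mitigated CH4 from 2010 to 2050
#'   (default 0.38); together with `ch4_2050` this fixes the 2010 level at
#'   `ch4_2050 / (1 - ch4_drop_2050)` (112.9 Mt/yr with defaults).
#' @param ch4_growth_2000s Fractional growth of livestock CH4 from 2000 to
#'   2010 (default 0.10).
#' @param ch4_2020 Livestock CH4 in 2020 (Mt/yr, default 115), shared by the
#'   mitigation and BAU pathways.
#' @param ch4_2100 Mitigated livestock CH4 in 2100 (Mt/yr, default 55).
#' @param bau_growth_2050 BAU CH4 in 2050 as a multiple of the 2010 level
#'   (default 1.3).
#' @param bau_after_2050 `"constant"` (default) holds BAU CH4 at its 2050
#'   level; `"linear"` continues the late 2040s growth increment.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(years = 2000:2100,
                            co2_2000 = 30, co2_2010 = 33, co2_2020 = 35,
                            co2_decline = 0.049,
                            co2_net_zero = 2055,
                            co2_floor_2100 = -10,
                            co2_budget = 580,
                            budget_start = 2018,
                            co2_calibration_year = 2042,
                            ch4_2050 = 70,
                            ch4_drop_2050 = 0.38,
                            ch4_growth_2000s = 0.10,
                            ch4_2020 = 115,
                            ch4_2100 = 55,
                            bau_growth_2050 = 1.3,
                            bau_after_2050 = c("constant", "linear")) {
  bau_after_2050 <- match.arg(bau_after_2050)
  cfg <- list(
    years = as.integer(years),
    co2_2000 = co2_2000, co2_2010 = co2_2010, co2_2020 = co2_2020,
    co2_decline = co2_decline, co2_net_zero = co2_net_zero,
    co2_floor_2100 = co2_floor_2100, co2_budget = co2_budget,
    budget_start = budget_start,
    co2_calibration_year = co2_calibration_year,
    ch4_2050 = ch4_2050, ch4_drop_2050 = ch4_drop_2050,
    ch4_growth_2000s = ch4_growth_2000s, ch4_2020 = ch4_2020,
    ch4_2100 = ch4_2100, bau_growth_2050 = bau_growth_2050,
    bau_after_2050 = bau_after_2050
  )
  cfg$ch4_2010 <- cfg$ch4_2050 / (1 - cfg$ch4_drop_2050)
  if (cfg$ch4_2050 < 0 || cfg$ch4_2100 < 0 || cfg$ch4_2010 < 0) {
    stop("configuration produces negative livestock CH4", call. = FALSE)
  }
  class(cfg) <- "scenario_config"
  cfg
}

# pre-2020 segments, shared by the mitigation/BAU generators and the backdrop
co2_pre2020_segment <- function(cfg, years) {
  a <- scenario_anchors(
    c(2000, 2010, 2020),
    c(cfg$co2_2000, cfg$co2_2010, cfg$co2_2020)
  )
  interpolate_anchors(a, years)
}

ch4_pre2020_segment <- function(cfg, years) {
  ch4_2000 <- cfg$ch4_2010 / (1 + cfg$ch4_growth_2000s)
  a <- scenario_anchors(
    c(2000, 2010, 2020),
    c(ch4_2000, cfg$ch4_2010, cfg$ch4_2020)
  )
  interpolate_anchors(a, years)
}

#' Stylized 1.5 degree-consistent mitigation scenario
#'
#' Deterministically generates the paired net CO2 and livestock CH4 pathways
#' of a stylized deep-mitigation scenario (see [scenario_config()] for the
#' anchor facts encoded). The net CO2 segment between 2030 and the net-zero
#' year contains one free anchor whose level is solved by root-finding so the
#' trapezoidal cumulative emission from `budget_start` to net-zero matches
#' the configured budget.
#'
#' @param config A [scenario_config()].
#' @return A list with elements `co2` and `ch4_livestock`, both
#'   [emissions_pathway()] objects.
#' @examples
#' sc <- make_mitigation_scenario()
#' pathway_value(sc$ch4_livestock, 2050) # 70
#' @export
make_mitigation_scenario <- function(config = scenario_config()) {
  cfg <- config
  years <- cfg$years
  nz <- cfg$co2_net_zero

  pre <- co2_pre2020_segment(cfg, years[years <= 2020])
  decl_years <- years[years > 2020 & years <= 2030]
  decl <- cfg$co2_2020 * (1 - cfg$co2_decline)^(decl_years - 2020)
  e2030 <- cfg$co2_2020 * (1 - cfg$co2_decline)^10

  mid_years <- years[years > 2030 & years <= nz]
  neg_years <- years[years > nz]
  neg_anchor_mid <- 0.6 * cfg$co2_floor_2100
  neg <- interpolate_anchors(
    scenario_anchors(c(nz, (nz + 2100) / 2, 2100), c(0, neg_anchor_mid, cfg$co2_floor_2100)),
    neg_years
  )

  assemble <- function(m) {
    mid <- interpolate_anchors(
      scenario_anchors(c(2030, cfg$co2_calibration_year, nz), c(e2030, m, 0)),
      mid_years
    )
    c(pre, decl, mid, neg)
  }
  budget_of <- function(m) {
    p <- emissions_pathway("co2_net", years, assemble(m))
    cumulative_to_net_zero(p, cfg$budget_start)
  }
  m_star <- stats::uniroot(
    function(m) budget_of(m) - cfg$co2_budget,
    lower = 0.05, upper = e2030 - 0.05, tol = 1e-8
  )$root
  co2 <- emissions_pathway("co2_net", years, assemble(m_star),
    label = "mitigation-1p5C"
  )

  ch4_pre <- ch4_pre2020_segment(cfg, years[years <= 2020])
  ch4_fut <- interpolate_anchors(
    scenario_anchors(
      c(2020, 2050, 2100),
      c(cfg$ch4_2020, cfg$ch4_2050, cfg$ch4_2100)
    ),
    years[years > 2020]
  )
  ch4_values <- c(ch4_pre, ch4_fut)
  if (any(ch4_values < 0)) {
    stop("configuration produces negative livestock CH4", call. = FALSE)
  }
  ch4 <- emissions_pathway("ch4_livestock", years, ch4_values,
    label = "mitigation-1p5C"
  )
  list(co2 = co2, ch4_livestock = ch4)
}

#' Business-as-usual livestock CH4 pathway
#'
#' Shares the mitigation scenario's pathway exactly for all years up to 2020,
#' then grows smoothly and monotonically to `bau_growth_2050` times the 2010
#' level by 2050 (146.8 Mt/yr with defaults). After 2050 the pathway is held
#' constant (default) or continues the late-2040s linear increment.
#'
#' @param config A [scenario_config()]; must be the same configuration used
#'   for [make_mitigation_scenario()] so the shared pre-2020 history is
#'   identical.
#' @return An [emissions_pathway()].
#' @examples
#' bau <- make_bau_livestock_ch4()
#' pathway_value(bau, 2050) # 1.3 * 112.9 = 146.8
#' @export
make_bau_livestock_ch4 <- function(config = scenario_config()) {
  cfg <- config
  years <- cfg$years
  pre <- ch4_pre2020_segment(cfg, years[years <= 2020])
  v2050 <- cfg$bau_growth_2050 * cfg$ch4_2010
  grow_years <- years[years > 2020 & years <= 2050]
  grow <- interpolate_anchors(
    scenario_anchors(c(2020, 2050), c(cfg$ch4_2020, v2050)),
    grow_years
  )
  post_years <- years[years > 2050]
  post <- if (cfg$bau_after_2050 == "constant") {
    rep(v2050, length(post_years))
  } else {
    slope <- (grow[length(grow)] - grow[length(grow) - 5L]) / 5
    v2050 + slope * (post_years - 2050)
  }
  values <- c(pre, grow, post)
  if (any(values < 0)) {
    stop("configuration produces negative livestock CH4", call. = FALSE)
  }
  emissions_pathway("ch4_livestock", years, values, label = "bau-livestock")
}

#' Stylized historical emissions backdrop, 1850-2020
#'
#' A smooth synthetic reconstruction of pre-2020 global net CO2 and livestock
#' CH4 emissions, anchored at round documented waypoints and joining the
#' scenario generators' shared 2000-2020 segment exactly. It exists only so
#' that legacy (pre-split) warming can be displayed alongside marginal
#' warming; it is a stylized approximation, not an observational series, and
#' marginal quantities never depend on it.
#'
#' @param gas `"co2_net"` or `"ch4_livestock"`.
#' @param config A [scenario_config()].
#' @return An [emissions_pathway()] over 1850-2020 with attribute
#'   `stylized = TRUE`.
#' @export
historical_backdrop <- function(gas = c("co2_net", "ch4_livestock"),
                                config = scenario_config()) {
  gas <- match.arg(gas)
  cfg <- config
  years_early <- 1850:2000
  if (gas == "co2_net") {
    early <- interpolate_anchors(
      scenario_anchors(
        c(1850, 1900, 1950, 1980, 2000),
        c(1, 3, 8, 22, cfg$co2_2000)
      ),
      years_early
    )
    late <- co2_pre2020_segment(cfg, 2001:2020)
  } else {
    ch4_2000 <- cfg$ch4_2010 / (1 + cfg$ch4_growth_2000s)
    early <- interpolate_anchors(
      scenario_anchors(
        c(1850, 1900, 1950, 1980, 2000),
        c(35, 45, 60, 85, ch4_2000)
      ),
      years_early
    )
    late <- ch4_pre2020_segment(cfg, 2001:2020)
  }
  p <- emissions_pathway(gas, 1850:2020, c(early, late),
    label = "stylized-history (synthetic)"
  )
  attr(p, "stylized") <- TRUE
  p
}
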