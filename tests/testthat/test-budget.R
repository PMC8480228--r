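test_that("net-zero year interpolates the downward crossing", {
  expect_equal(net_zero_year(mk("co2_net", 2040:2041, c(2, -2))), 2040.5)
  expect_equal(net_zero_year(mk("co2_net", 2040:2042, c(4, 1, -3))), 2041.25)
  # exact zero hit is the net-zero year
  expect_equal(net_zero_year(mk("co2_net", 2040:2042, c(2, 0, -1))), 2041)
  # never crosses -> explicit NA, not an error
  expect_true(is.na(net_zero_year(mk("co2_net", 2040:2045, rep(5, 6)))))
})

test_that("geometric reduction rate matches its closed form", {
  const <- mk("co2_net", 2020:2030, rep(7, 11))
  expect_equal(annual_reduction_rate(const, 2020, 2030), 0)
  half <- mk("co2_net", 2020:2030, seq(100, 50, length.out = 11))
  expect_equal(annual_reduction_rate(half, 2020, 2030), 100 * (1 - 0.5^0.1))
  expect_equal(annual_reduction_rate(half, 2020, 2030), 6.70, tolerance = 1e-3)
  neg <- mk("co2_net", 2020:2030, seq(10, -10, length.out = 11))
  expect_error(annual_reduction_rate(neg, 2020, 2030), "strictly positive")
})

test_that("cumulative-to-net-zero is the trapezoidal integral to the crossing", {
  tri <- mk("co2_net", 2020:2031, c(seq(10, 0, length.out = 11), -1))
  expect_equal(cumulative_to_net_zero(tri, 2020), 50)
  # integral additivity over a split interval
  p <- scenario$co2
  nz <- net_zero_year(p)
  whole <- cumulative_to_net_zero(p, 2018)
  part1 <- sum((p$values[match(2018:2029, p$years)] +
    p$values[match(2019:2030, p$years)]) / 2)
  part2 <- cumulative_to_net_zero(p, 2030)
  expect_equal(whole, part1 + part2, tolerance = 1e-9)
  # never-crossing propagates NA
  expect_true(is.na(cumulative_to_net_zero(mk("co2_net", 2020:2025, rep(1, 6)), 2020)))
})

test_that("budget fractions are exact quotients", {
  expect_equal(budget_fraction(136, 1170), 100 * 136 / 1170)
  expect_equal(budget_fraction(136, 1170), 11.6, tolerance = 0.005)
  expect_equal(budget_fraction(136, 580), 23.4, tolerance = 0.005)
  expect_equal(budget_fraction(0, 580), 0)
  expect_error(budget_fraction(10, 0), "> 0")
})

test_that("budget report deltas are antisymmetric", {
  a <- budget_report(scenario$co2)
  b <- budget_report(ch4margin:::co2_family_member(scenario$co2, 1.5))
  d_ab <- budget_report_delta(a, b)
  d_ba <- budget_report_delta(b, a)
  for (f in names(d_ab)) expect_equal(d_ab[[f]], -d_ba[[f]])
  # report internals are consistent with the standalone operations
  expect_equal(a$cumulative, cumulative_to_net_zero(scenario$co2, 2018), tolerance = 1e-9)
  expect_equal(a$net_zero_year, net_zero_year(scenario$co2))
})

test_that("the inversion identity case returns the reference pathway", {
  inv <- adjust_co2_for_ch4(
    scenario$co2, scenario$ch4_livestock, scenario$ch4_livestock, default_em
  )
  expect_true(inv$converged)
  expect_equal(inv$scale, 1, tolerance = 1e-3)
  expect_equal(inv$adjusted$values, scenario$co2$values, tolerance = 1e-3)
  expect_equal(inv$delta$cumulative, 0, tolerance = 0.5)
  expect_lt(inv$residual, 1e-3)
})

test_that("the inversion rejects a cooler alternative and reports its residual", {
  cooler <- scenario$ch4_livestock
  cooler$values <- cooler$values * 0.5
  expect_error(
    adjust_co2_for_ch4(scenario$co2, scenario$ch4_livestock, cooler, default_em),
    "must be >="
  )
  inv <- suppressWarnings(
    adjust_co2_for_ch4(scenario$co2, scenario$ch4_livestock, bau_ch4, default_em)
  )
  expect_true(is.finite(inv$residual))
  # matched combined warming: residual is far below the unmatched CH4 gap
  gap <- max(abs(
    warming_from_emissions(bau_ch4, default_em)$values -
      warming_from_emissions(scenario$ch4_livestock, default_em)$values
  ))
  expect_lt(inv$residual, 0.15 * gap)
})

test_that("a uniformly higher CH4 alternative never yields a larger budget", {
  mit <- scenario$ch4_livestock
  budgets <- vapply(c(0, 10, 25), function(extra) {
    alt <- mit
    up <- alt$years > 2020
    alt$values[up] <- alt$values[up] + extra
    inv <- suppressWarnings(
      adjust_co2_for_ch4(scenario$co2, mit, alt, default_em)
    )
    inv$adjusted_report$cumulative
  }, numeric(1L))
  expect_true(all(diff(budgets) < 0))
})

test_that("emergent TCRE is constant across pulse sizes in linearized mode", {
  per_gt <- vapply(c(100, 500, 1000, 2000), function(mass) {
    p <- pulse_pathway("co2_net", 70, mass)
    warming_from_emissions(p, default_em)$values[71L] / mass
  }, numeric(1L))
  expect_lt(diff(range(per_gt)) / mean(per_gt), 1e-9)
  # and its magnitude is a plausible warming per 1000 Gt CO2
  expect_gt(per_gt[1L] * 1000, 0.3)
  expect_lt(per_gt[1L] * 1000, 0.8)
})

test_that("the stabilizing CH4 decline rate matches a brute-force grid scan", {
  rate <- stabilizing_decline_rate(115, default_em)
  # brute-force scan over r in [0, 1] %/yr at 0.01 pp resolution
  drift_at <- function(r) {
    years <- 1920:2060
    decline <- (1 - r)^(pmax(years - 2020, 0))
    p <- mk("ch4_livestock", years, 115 * decline)
    tw <- warming_from_emissions(p, default_em)
    pathway_value(tw, 2060) - pathway_value(tw, 2020)
  }
  grid <- seq(0, 0.01, by = 1e-4)
  best <- 100 * grid[which.min(abs(vapply(grid, drift_at, numeric(1L))))]
  expect_equal(rate, best, tolerance = 0.01 / best)
  # rate is insensitive to the (linear) baseline level
  expect_equal(stabilizing_decline_rate(230, default_em), rate, tolerance = 1e-6)
})

test_that("with fast thermal equilibration constant emissions already stabilize", {
  fast <- climate_emulator(thermal = thermal_params(q = c(0.631, 0.429), d = c(1, 2)))
  expect_lt(stabilizing_decline_rate(115, fast), 0.01)
  expect_error(stabilizing_decline_rate(-3, default_em))
  expect_error(stabilizing_decline_rate(115, default_em, window = c(2020, 2040)), "40 years")
})
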