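test_that("parameter validation enforces conservation and positivity", {
  expect_error(gas_cycle_params(co2_irf_a0 = 0.3), "sum to 1")
  expect_error(gas_cycle_params(ch4_lifetime = -1), "> 0")
  expect_error(gas_cycle_params(ch4_indirect = 0.9), ">= 1")
  expect_error(thermal_params(d = c(400, 8)), "d\\[1\\]")
  # conservation holds for the default IRF
  gc <- gas_cycle_params()
  expect_equal(gc$co2_irf_a0 + sum(gc$co2_irf_a), 1, tolerance = 1e-12)
  # kernel at age zero: the instantaneous jump equals mass / factor exactly
  expect_equal(ch4margin:::co2_irf(0, gc), 1)
})

test_that("CO2 concentration follows the IRF closed form", {
  # zero emissions -> zero anomaly
  z <- co2_concentration(mk("co2_net", 2000:2010, rep(0, 11)), default_em)
  expect_equal(z$values, rep(0, 11))
  # 1000 Gt pulse: persistent anomaly tends to 1000/7.814 * a0 = 27.8 ppm
  gc <- default_em$gas_cycle
  expect_equal(1000 / gc$co2_per_ppm * gc$co2_irf_a0, 27.8, tolerance = 1e-3)
  p <- pulse_pathway("co2_net", n_years = 2000, mass = 1000)
  conc <- co2_concentration(p, default_em)
  expect_equal(
    conc$values[length(conc$values)],
    1000 / gc$co2_per_ppm * ch4margin:::co2_irf(2001 - 0.5, gc)
  )
  expect_equal(conc$values[length(conc$values)], 27.8, tolerance = 0.01)
  # each year-end value equals the analytic convolution of the pulse
  expect_equal(
    conc$values[1:50],
    1000 / gc$co2_per_ppm * ch4margin:::co2_irf((1:50) - 0.5, gc)
  )
})

test_that("CH4 concentration follows the single-box closed form", {
  gc <- default_em$gas_cycle
  tau <- gc$ch4_lifetime
  # constant 27.5 Mt/yr -> steady state E*tau/m = 120 ppb
  const <- mk("ch4_livestock", 1800:2000, rep(27.5, 201))
  conc <- ch4_concentration(const, default_em)
  steady_exact <- 27.5 / gc$ch4_per_ppb * exp(-0.5 / tau) / (1 - exp(-1 / tau))
  expect_equal(conc$values[201], steady_exact, tolerance = 1e-6)
  expect_equal(conc$values[201], 27.5 * tau / gc$ch4_per_ppb, tolerance = 1e-3)
  expect_equal(conc$values[201], 120, tolerance = 1e-3)
  # 275 Mt pulse decays as 100 ppb * exp(-t/tau) (mid-year pulse timing)
  pulse <- ch4_concentration(pulse_pathway("ch4_livestock", 80, 275), default_em)
  expect_equal(pulse$values[1:60], 100 * exp(-((1:60) - 0.5) / tau))
  # wrong gas errors
  expect_error(ch4_concentration(mk("co2_net", 2000:2001, c(1, 1))), "ch4_livestock")
  expect_error(co2_concentration(mk("ch4_livestock", 2000:2001, c(1, 1))), "co2_net")
})

test_that("forcing is the stated product / logarithm of the anomaly", {
  s <- annual_series(2000:2001, c(0, 100), "concentration", "ppb")
  f <- forcing_from_concentration(s, "ch4_livestock", default_em)
  expect_equal(f$values, c(0, 100 * 3.63e-4 * 1.65))
  expect_equal(f$values[2L], 0.0599, tolerance = 1e-3)
  s2 <- annual_series(2000:2001, c(0, 10), "concentration", "ppm")
  f2 <- forcing_from_concentration(s2, "co2_net", default_em)
  expect_equal(f2$values[2L], 0.134)
  em_log <- climate_emulator(gas_cycle_params(co2_forcing = "log"))
  f3 <- forcing_from_concentration(s2, "co2_net", em_log)
  expect_equal(f3$values[2L], 5.35 * log(410 / 400))
})

test_that("temperature from a step forcing matches the two-mode closed form", {
  th <- default_em$thermal
  f <- annual_series(1:200, rep(1, 200), "forcing", "W/m2")
  tw <- temperature_from_forcing(f, default_em)
  # after 10 years of unit forcing: q1(1-e^(-10/8.4)) + q2(1-e^(-10/409.5))
  expect_equal(tw$values[10L], sum(th$q * (1 - exp(-10 / th$d))))
  expect_equal(tw$values[10L], 0.449, tolerance = 2e-3)
  # asymptote: sum(q) = 1.06
  expect_equal(tw$values[200L], sum(th$q * (1 - exp(-200 / th$d))))
  expect_lt(tw$values[200L], sum(th$q))
  expect_equal(sum(th$q), 1.06)
  # monotone non-decreasing under step forcing
  expect_true(all(diff(tw$values) > 0))
})

test_that("kernels are linear and time-shift equivariant", {
  set.seed(42)
  for (gas in c("co2_net", "ch4_livestock")) {
    for (rep in 1:5) {
      a <- mk(gas, 2000:2060, runif(61, 0, 30))
      b <- mk(gas, 2000:2060, runif(61, 0, 30))
      ab <- mk(gas, 2000:2060, a$values + b$values)
      wa <- warming_from_emissions(a, default_em)
      wb <- warming_from_emissions(b, default_em)
      wab <- warming_from_emissions(ab, default_em)
      expect_equal(wab$values, wa$values + wb$values, tolerance = 1e-12)
      # shifting emissions by k years shifts the response by k years
      k <- 7L
      shifted <- mk(gas, 2000:2060, c(rep(0, k), a$values[1:(61 - k)]))
      ws <- warming_from_emissions(shifted, default_em)
      expect_equal(ws$values[(k + 1):61], wa$values[1:(61 - k)], tolerance = 1e-12)
      # scaling
      w2 <- warming_from_emissions(mk(gas, 2000:2060, 2 * a$values), default_em)
      expect_equal(w2$values, 2 * wa$values, tolerance = 1e-12)
    }
  }
})

test_that("nonnegative emissions give nonnegative concentration and warming", {
  set.seed(7)
  for (rep in 1:5) {
    p <- mk("ch4_livestock", 2000:2100, runif(101, 0, 200))
    expect_true(all(ch4_concentration(p, default_em)$values >= 0))
    expect_true(all(warming_from_emissions(p, default_em)$values >= 0))
  }
})

test_that("annual discretization tracks a fine-time-step simulation", {
  # the annual scheme carries a first-order bias from holding each year's
  # forcing at its year-end value; pulse responses at t >= 10 stay within
  # 6% of the peak response of a dt = 0.1 simulation of the same kernels
  for (gas in c("co2_net", "ch4_livestock")) {
    p <- pulse_pathway(gas, 110, 1)
    tw <- warming_from_emissions(p, default_em)
    peak <- max(tw$values)
    for (h in c(10, 20, 50, 100)) {
      fine <- fine_pulse_temperature(gas, 1, h, default_em, dt = 0.1)
      expect_lt(abs(tw$values[h + 1L] - fine), 0.06 * peak)
    }
  }
})

test_that("pulse AGTP matches the independently coded double-exponential closed form", {
  # discrete 1 Mt CH4 pulse vs the analytic expression at the mid-aligned age
  p <- pulse_pathway("ch4_livestock", 110, 1)
  tw <- warming_from_emissions(p, default_em)
  an <- metric("ch4_livestock", 100 - 0.5, default_em, type = "AGTP")
  expect_equal(tw$values[101L], an, tolerance = 0.02)
  # zero-mass pulse
  expect_equal(metric("ch4_livestock", 100, default_em, type = "AGTP", mass = 0), 0)
})

test_that("GWP100 of CH4 is AR5-consistent and matches a numerical integration oracle", {
  expect_equal(metric("co2_net", 100, default_em), 1)
  expect_equal(metric("co2_net", 20, default_em), 1)
  g100 <- metric("ch4_livestock", 100, default_em)
  expect_gte(g100, 25)
  expect_lte(g100, 32)
  # independent numerical route through the same kernels
  gc <- default_em$gas_cycle
  irf <- function(t) gc$co2_irf_a0 + colSums(gc$co2_irf_a * exp(-outer(1 / gc$co2_irf_tau, t)))
  agwp_co2 <- stats::integrate(function(t) {
    gc$co2_eff_per_ppm * irf(t) * 1e-3 / gc$co2_per_ppm
  }, 0, 100, rel.tol = 1e-10)$value
  agwp_ch4 <- stats::integrate(function(t) {
    gc$ch4_efficiency * gc$ch4_indirect / gc$ch4_per_ppb * exp(-t / gc$ch4_lifetime)
  }, 0, 100, rel.tol = 1e-10)$value
  expect_equal(g100, agwp_ch4 / agwp_co2, tolerance = 1e-8)
  expect_error(metric("ch4_livestock", -5, default_em), "horizon")
})

test_that("emulator object methods report the parameter set", {
  cf <- coef(default_em)
  expect_equal(unname(cf["ch4_lifetime"]), 12)
  expect_equal(unname(cf["q1"] + cf["q2"]), 1.06)
  expect_output(print(default_em), "CO2 IRF")
  t1 <- predict(default_em, scenario$co2)
  t2 <- warming_from_emissions(scenario$co2, default_em)
  expect_equal(t1$values, t2$values)
  expect_s3_class(predict(default_em, scenario$co2, what = "forcing"), "forcing_series")
})

test_that("YAML parameter round trip preserves the emulator", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  em <- climate_emulator(
    gas_cycle_params(ch4_lifetime = 11.8, ch4_indirect = 1.4),
    thermal_params(q = c(0.5, 0.3), d = c(4, 300))
  )
  write_emulator_params(em, tmp)
  back <- read_emulator_params(tmp)
  expect_equal(coef(back), coef(em))
  expect_error(read_emulator_params(file.path(tempdir(), "nope.yaml")), "not found")
})
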