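# shared objects: the default emulator and the bundled scenario pair
default_em <- climate_emulator()
scenario <- make_mitigation_scenario()
bau_ch4 <- make_bau_livestock_ch4()

# small constructor for ad-hoc pathways on an arbitrary axis
mk <- function(gas, years, values) emissions_pathway(gas, years, values, "test")

# unit pulse pathway: 1 unit in the first year, zeros after
pulse_pathway <- function(gas, n_years = 120, mass = 1) {
  mk(gas, seq_len(n_years + 1L) + 1999L, c(mass, rep(0, n_years)))
}

# fine-time-step reference simulation of the same continuous kernels
# (mid-cell emissions, cell-constant forcing), used to check that the
# annual discretization has converged
fine_pulse_temperature <- function(gas, mass, horizon, em, dt = 0.1) {
  gc <- em$gas_cycle
  th <- em$thermal
  nt <- round(horizon / dt)
  ages <- (seq_len(nt) - 0.5) * dt
  conc <- if (gas == "co2_net") {
    kv <- (gc$co2_irf_a0 + colSums(gc$co2_irf_a * exp(-outer(1 / gc$co2_irf_tau, ages)))) /
      gc$co2_per_ppm
    mass * kv
  } else {
    mass * exp(-ages / gc$ch4_lifetime) / gc$ch4_per_ppb
  }
  f <- if (gas == "co2_net") {
    gc$co2_eff_per_ppm * conc # mass in Gt, like the annual emulator input
  } else {
    gc$ch4_efficiency * gc$ch4_indirect * conc
  }
  lags <- seq_len(nt) - 1
  g <- numeric(nt)
  for (j in seq_along(th$q)) {
    g <- g + th$q[j] * (exp(-lags * dt / th$d[j]) - exp(-(lags + 1) * dt / th$d[j]))
  }
  stats::convolve(f, rev(g), type = "open")[nt]
}
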