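#' Pulse-response climate emulator
#'
#' Constructs the forward emulator mapping annual emission pathways to
#' concentration, radiative-forcing and temperature anomalies. The chain is
#' emissions -> concentration (CO2: impulse-response convolution; CH4:
#' single-box decay) -> forcing (linear or logarithmic for CO2; linear with
#' an indirect-effects multiplier for CH4) -> temperature (two-mode thermal
#' convolution). Emissions are applied at mid-year; concentrations, forcings
#' and temperatures are reported at year-end. In the default linearized CO2
#' forcing mode every kernel is linear and time-shift equivariant, so
#' warming is additive across pathways and marginal decompositions are exact.
#'
#' @param gas_cycle A [gas_cycle_params()] object.
#' @param thermal A [thermal_params()] object.
#' @return An object of class `climate_emulator` with elements `gas_cycle`
#'   and `thermal`.
#' @examples
#' em <- climate_emulator()
#' sc <- make_mitigation_scenario()
#' t_co2 <- predict(em, sc$co2)
#' pathway_value(t_co2, 2050)
#' @seealso [predict.climate_emulator()], [warming_from_emissions()]
#' @export
climate_emulator <- function(gas_cycle = gas_cycle_params(),
                             thermal = thermal_params()) {
  stopifnot(inherits(gas_cycle, "gas_cycle_params"), inherits(thermal, "thermal_params"))
  structure(list(gas_cycle = gas_cycle, thermal = thermal),
    class = "climate_emulator"
  )
}

#' @export
print.climate_emulator <- function(x, ...) {
  gc <- x$gas_cycle
  th <- x$thermal
  cat("<climate_emulator>\n")
  cat(sprintf(
    "  CO2 IRF: a0 = %.4f, a = (%s), tau = (%s) yr, %.3f Gt/ppm\n",
    gc$co2_irf_a0, paste(format(gc$co2_irf_a), collapse = ", "),
    paste(format(gc$co2_irf_tau), collapse = ", "), gc$co2_per_ppm
  ))
  cat(sprintf(
    "  CH4 box: tau = %.1f yr, %.2f Mt/ppb, RE %.3g W/m2/ppb x %.2f indirect\n",
    gc$ch4_lifetime, gc$ch4_per_ppb, gc$ch4_efficiency, gc$ch4_indirect
  ))
  cat(sprintf(
    "  CO2 forcing: %s (%s)\n", gc$co2_forcing,
    if (gc$co2_forcing == "linear") {
      sprintf("%.4f W/m2/ppm about %.0f ppm", gc$co2_eff_per_ppm, gc$co2_ref_ppm)
    } else {
      sprintf("alpha = %.2f W/m2, C0 = %.0f ppm", gc$co2_log_alpha, gc$co2_ref_ppm)
    }
  ))
  cat(sprintf(
    "  thermal: q = (%.3f, %.3f) K/(W/m2), d = (%.1f, %.1f) yr; equilibrium %.2f K/(W/m2)\n",
    th$q[1L], th$q[2L], th$d[1L], th$d[2L], sum(th$q)
  ))
  invisible(x)
}

#' @export
summary.climate_emulator <- function(object, ...) {
  cat("Pulse-response climate emulator\n\n")
  print(object)
  cat(sprintf(
    "\nDerived metrics (100-yr horizon): GWP100(CH4) = %.1f, AGTP100(CH4) = %.3g K/Mt\n",
    metric("ch4_livestock", 100, object, type = "GWP"),
    metric("ch4_livestock", 100, object, type = "AGTP")
  ))
  invisible(object)
}

#' @export
coef.climate_emulator <- function(object, ...) {
  gc <- object$gas_cycle
  th <- object$thermal
  c(
    co2_irf_a0 = gc$co2_irf_a0,
    co2_irf_a1 = gc$co2_irf_a[1L], co2_irf_a2 = gc$co2_irf_a[2L],
    co2_irf_a3 = gc$co2_irf_a[3L],
    co2_irf_tau1 = gc$co2_irf_tau[1L], co2_irf_tau2 = gc$co2_irf_tau[2L],
    co2_irf_tau3 = gc$co2_irf_tau[3L],
    co2_per_ppm = gc$co2_per_ppm,
    ch4_lifetime = gc$ch4_lifetime, ch4_per_ppb = gc$ch4_per_ppb,
    ch4_efficiency = gc$ch4_efficiency, ch4_indirect = gc$ch4_indirect,
    co2_eff_per_ppm = gc$co2_eff_per_ppm, co2_ref_ppm = gc$co2_ref_ppm,
    q1 = th$q[1L], q2 = th$q[2L], d1 = th$d[1L], d2 = th$d[2L]
  )
}

# airborne fraction of a CO2 pulse after t years
co2_irf <- function(t, gc) {
  out <- rep(gc$co2_irf_a0, length(t))
  for (k in seq_along(gc$co2_irf_a)) {
    out <- out + gc$co2_irf_a[k] * exp(-t / gc$co2_irf_tau[k])
  }
  out
}

# discrete convolution of annual inputs with a kernel sampled at given ages;
# conv_kernel(E, k)[i] = sum_{j<=i} E[j] * k[i-j+1]. Direct summation (not
# FFT) so that output i depends only on inputs up to i: zero-emission
# prefixes give exactly zero response and nonnegative inputs can never
# produce spurious negative round-off.
conv_kernel <- function(x, kvals) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    out[i] <- sum(x[seq_len(i)] * kvals[i:1])
  }
  out
}

#' CO2 concentration anomaly from a net CO2 pathway
#'
#' Discrete convolution of annual emissions (applied mid-year, converted at
#' `co2_per_ppm`) with the impulse-response airborne fraction
#' \eqn{a_0 + \sum_i a_i e^{-t/\tau_i}}; reported at year-end. Linear in
#' emissions.
#'
#' @param pathway An [emissions_pathway()] with gas `"co2_net"`.
#' @param emulator A [climate_emulator()].
#' @return A `concentration_series` (ppm anomaly).
#' @export
co2_concentration <- function(pathway, emulator = climate_emulator()) {
  stopifnot(inherits(pathway, "emissions_pathway"))
  if (pathway$gas != "co2_net") {
    stop("co2_concentration() requires a co2_net pathway", call. = FALSE)
  }
  gc <- emulator$gas_cycle
  ages <- seq_along(pathway$years) - 0.5 # mid-year emission, year-end report
  kvals <- co2_irf(ages, gc) / gc$co2_per_ppm
  annual_series(pathway$years, conv_kernel(pathway$values, kvals),
    kind = "concentration", unit = "ppm", label = pathway$label
  )
}

#' CH4 concentration anomaly from a CH4 pathway
#'
#' Single-box decay: the anomaly obeys \eqn{dC/dt = E/m - C/\tau},
#' discretized annually with mid-year emission pulses, so a constant
#' emission `E` asymptotes to \eqn{E\tau/m} and a pulse decays as
#' \eqn{e^{-t/\tau}}. Linear in emissions.
#'
#' @param pathway An [emissions_pathway()] with gas `"ch4_livestock"` (any
#'   CH4 series).
#' @param emulator A [climate_emulator()].
#' @return A `concentration_series` (ppb anomaly).
#' @export
ch4_concentration <- function(pathway, emulator = climate_emulator()) {
  stopifnot(inherits(pathway, "emissions_pathway"))
  if (pathway$gas != "ch4_livestock") {
    stop("ch4_concentration() requires a ch4_livestock pathway", call. = FALSE)
  }
  gc <- emulator$gas_cycle
  ages <- seq_along(pathway$years) - 0.5
  kvals <- exp(-ages / gc$ch4_lifetime) / gc$ch4_per_ppb
  annual_series(pathway$years, conv_kernel(pathway$values, kvals),
    kind = "concentration", unit = "ppb", label = pathway$label
  )
}

#' Radiative forcing from a concentration anomaly
#'
#' CH4: direct radiative efficiency times anomaly times the indirect-effects
#' multiplier. CO2: linearized efficiency times anomaly (default), or
#' logarithmic \eqn{\alpha \log((C_0 + \Delta C)/C_0)} when the emulator's
#' forcing mode is `"log"`.
#'
#' @param conc A `concentration_series` from [co2_concentration()] or
#'   [ch4_concentration()].
#' @param gas `"co2_net"` or `"ch4_livestock"`.
#' @param emulator A [climate_emulator()].
#' @return A `forcing_series` (W/m2).
#' @export
forcing_from_concentration <- function(conc, gas, emulator = climate_emulator()) {
  stopifnot(inherits(conc, "concentration_series"))
  gc <- emulator$gas_cycle
  values <- if (gas == "ch4_livestock") {
    gc$ch4_efficiency * gc$ch4_indirect * conc$values
  } else if (gas == "co2_net") {
    if (gc$co2_forcing == "linear") {
      gc$co2_eff_per_ppm * conc$values
    } else {
      if (gc$co2_ref_ppm <= 0) stop("reference concentration must be > 0", call. = FALSE)
      gc$co2_log_alpha * log((gc$co2_ref_ppm + conc$values) / gc$co2_ref_ppm)
    }
  } else {
    stop("unknown gas: ", gas, call. = FALSE)
  }
  annual_series(conc$years, values, kind = "forcing", unit = "W/m2", label = conc$label)
}

#' Temperature anomaly from a forcing series
#'
#' Convolution of the forcing (held constant within each year) with the
#' thermal impulse response \eqn{R(t) = \sum_j (q_j/d_j) e^{-t/d_j}},
#' integrated exactly over each year, so a step forcing `F` sustained for
#' `n` years gives exactly \eqn{F \sum_j q_j (1 - e^{-n/d_j})} and
#' asymptotes to \eqn{F \sum_j q_j}.
#'
#' @param forcing A `forcing_series`.
#' @param emulator A [climate_emulator()] (its `thermal` component is used).
#' @return A `temperature_series` (deg C anomaly).
#' @export
temperature_from_forcing <- function(forcing, emulator = climate_emulator()) {
  stopifnot(inherits(forcing, "forcing_series"))
  th <- emulator$thermal
  lags <- seq_along(forcing$years) - 1
  gvals <- numeric(length(lags))
  for (j in seq_along(th$q)) {
    gvals <- gvals + th$q[j] * (exp(-lags / th$d[j]) - exp(-(lags + 1) / th$d[j]))
  }
  annual_series(forcing$years, conv_kernel(forcing$values, gvals),
    kind = "temperature", unit = "degC", label = forcing$label
  )
}

#' Warming from an emissions pathway
#'
#' Composes the concentration, forcing and temperature kernels. With the
#' default linearized CO2 forcing the composition is linear in emissions, so
#' `warming(A + B) = warming(A) + warming(B)`.
#'
#' @param pathway An [emissions_pathway()].
#' @param emulator A [climate_emulator()].
#' @return A `temperature_series` (deg C anomaly relative to the pathway
#'   start).
#' @export
warming_from_emissions <- function(pathway, emulator = climate_emulator()) {
  conc <- if (pathway$gas == "co2_net") {
    co2_concentration(pathway, emulator)
  } else {
    ch4_concentration(pathway, emulator)
  }
  f <- forcing_from_concentration(conc, pathway$gas, emulator)
  temperature_from_forcing(f, emulator)
}

#' Predict concentration, forcing or temperature from an emissions pathway
#'
#' @param object A [climate_emulator()].
#' @param pathway An [emissions_pathway()].
#' @param what One of `"temperature"` (default), `"forcing"`,
#'   `"concentration"`.
#' @param ... Unused.
#' @return An `annual_series` of the requested kind.
#' @export
predict.climate_emulator <- function(object, pathway,
                                     what = c("temperature", "forcing", "concentration"),
                                     ...) {
  what <- match.arg(what)
  conc <- if (pathway$gas == "co2_net") {
    co2_concentration(pathway, object)
  } else {
    ch4_concentration(pathway, object)
  }
  if (what == "concentration") {
    return(conc)
  }
  f <- forcing_from_concentration(conc, pathway$gas, object)
  if (what == "forcing") {
    return(f)
  }
  temperature_from_forcing(f, object)
}

# analytic time-integrated forcing of a 1 Mt pulse up to horizon H (W/m2 yr)
agwp_analytic <- function(gas, H, emulator) {
  gc <- emulator$gas_cycle
  if (gas == "co2_net") {
    integral <- gc$co2_irf_a0 * H +
      sum(gc$co2_irf_a * gc$co2_irf_tau * (1 - exp(-H / gc$co2_irf_tau)))
    # 1 Mt = 1e-3 Gt; linearized efficiency is used for metrics
    gc$co2_eff_per_ppm * integral * 1e-3 / gc$co2_per_ppm
  } else if (gas == "ch4_livestock") {
    tau <- gc$ch4_lifetime
    gc$ch4_efficiency * gc$ch4_indirect / gc$ch4_per_ppb *
      tau * (1 - exp(-H / tau))
  } else {
    stop("unknown gas: ", gas, call. = FALSE)
  }
}

# analytic pulse temperature at horizon H for a 1 Mt pulse (K): the
# convolution of exponential forcing modes with the two thermal modes
agtp_analytic <- function(gas, H, emulator) {
  gc <- emulator$gas_cycle
  th <- emulator$thermal
  mode_term <- function(tau, q, d) {
    if (abs(tau - d) < 1e-9) {
      q * H * exp(-H / d) / d
    } else {
      q * tau / (tau - d) * (exp(-H / tau) - exp(-H / d))
    }
  }
  if (gas == "co2_net") {
    A <- gc$co2_eff_per_ppm * 1e-3 / gc$co2_per_ppm # forcing per Mt at t=0
    out <- 0
    for (j in seq_along(th$q)) {
      out <- out + A * gc$co2_irf_a0 * th$q[j] * (1 - exp(-H / th$d[j]))
      for (k in seq_along(gc$co2_irf_a)) {
        out <- out + A * gc$co2_irf_a[k] *
          mode_term(gc$co2_irf_tau[k], th$q[j], th$d[j])
      }
    }
    out
  } else if (gas == "ch4_livestock") {
    A <- gc$ch4_efficiency * gc$ch4_indirect / gc$ch4_per_ppb
    out <- 0
    for (j in seq_along(th$q)) {
      out <- out + A * mode_term(gc$ch4_lifetime, th$q[j], th$d[j])
    }
    out
  } else {
    stop("unknown gas: ", gas, call. = FALSE)
  }
}

#' Emission metrics: AGWP, AGTP and GWP
#'
#' Closed-form pulse metrics for the emulator's parameter set. AGWP is the
#' time-integrated radiative forcing of a 1 Mt pulse up to the horizon
#' (W/m2 yr per Mt); AGTP is the pulse temperature response at the horizon
#' (K per Mt); GWP is the ratio of the gas's AGWP to that of CO2 at equal
#' emitted mass (dimensionless; 1 for CO2 at any horizon). CO2 forcing is
#' linearized for metric purposes.
#'
#' @param gas `"co2_net"` or `"ch4_livestock"`.
#' @param horizon Time horizon in years (> 0).
#' @param emulator A [climate_emulator()].
#' @param type `"GWP"` (default), `"AGWP"` or `"AGTP"`.
#' @param mass Pulse mass in Mt for AGWP/AGTP (default 1).
#' @return A single numeric value.
#' @examples
#' metric("ch4_livestock", 100) # GWP100, about 29 with defaults
#' @export
metric <- function(gas, horizon, emulator = climate_emulator(),
                   type = c("GWP", "AGWP", "AGTP"), mass = 1) {
  type <- match.arg(type)
  if (horizon <= 0) stop("horizon must be > 0", call. = FALSE)
  gas <- match.arg(gas, c("co2_net", "ch4_livestock"))
  switch(type,
    AGWP = mass * agwp_analytic(gas, horizon, emulator),
    AGTP = mass * agtp_analytic(gas, horizon, emulator),
    GWP = agwp_analytic(gas, horizon, emulator) /
      agwp_analytic("co2_net", horizon, emulator)
  )
}
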