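#' Gas-cycle parameters
#'
#' Coefficients of the impulse-response carbon cycle and the single-box
#' methane model, plus radiative-forcing coefficients. Defaults are an
#' AR5-era pulse-response convention approximating a median reduced-
#' complexity model response:
#' * CO2 airborne-fraction IRF \eqn{a_0 + \sum_i a_i e^{-t/\tau_i}} with
#'   `a0 = 0.2173`, `a = (0.2240, 0.2824, 0.2763)`,
#'   `tau = (394.4, 36.54, 4.304)` years (the fractions sum to 1);
#' * 7.814 Gt CO2 per ppm; 2.75 Mt CH4 per ppb;
#' * CH4 perturbation lifetime 12.0 years;
#' * CH4 direct radiative efficiency 3.63e-4 W/m2/ppb with an indirect-
#'   effects multiplier of 1.65 (tropospheric ozone and stratospheric water
#'   vapour);
#' * CO2 forcing either linearized about a 400 ppm reference at
#'   0.0134 W/m2/ppm (default; keeps the marginal decomposition exact) or
#'   logarithmic, \eqn{\alpha \log((C_0 + \Delta C)/C_0)} with
#'   `alpha = 5.35` W/m2.
#'
#' @param co2_irf_a0 Persistent airborne fraction.
#' @param co2_irf_a Amplitudes of the three decaying modes.
#' @param co2_irf_tau Time constants of the decaying modes (years).
#' @param co2_per_ppm Gt CO2 per ppm.
#' @param ch4_lifetime CH4 perturbation lifetime (years).
#' @param ch4_per_ppb Mt CH4 per ppb.
#' @param ch4_efficiency CH4 direct radiative efficiency (W/m2/ppb).
#' @param ch4_indirect Dimensionless multiplier (>= 1) for indirect CH4
#'   forcing.
#' @param co2_forcing `"linear"` or `"log"`.
#' @param co2_eff_per_ppm Linearized CO2 radiative efficiency (W/m2/ppm).
#' @param co2_ref_ppm Reference concentration for logarithmic forcing (ppm).
#' @param co2_log_alpha Logarithmic forcing coefficient (W/m2).
#' @return A list of class `gas_cycle_params`.
#' @export
gas_cycle_params <- function(co2_irf_a0 = 0.2173,
                             co2_irf_a = c(0.2240, 0.2824, 0.2763),
                             co2_irf_tau = c(394.4, 36.54, 4.304),
                             co2_per_ppm = 7.814,
                             ch4_lifetime = 12.0,
                             ch4_per_ppb = 2.75,
                             ch4_efficiency = 3.63e-4,
                             ch4_indirect = 1.65,
                             co2_forcing = c("linear", "log"),
                             co2_eff_per_ppm = 0.0134,
                             co2_ref_ppm = 400,
                             co2_log_alpha = 5.35) {
  co2_forcing <- match.arg(co2_forcing)
  if (abs(co2_irf_a0 + sum(co2_irf_a) - 1) > 1e-9) {
    stop("CO2 IRF fractions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  if (any(co2_irf_tau <= 0) || ch4_lifetime <= 0) {
    stop("all lifetimes must be > 0", call. = FALSE)
  }
  if (ch4_indirect < 1) stop("indirect-effects multiplier must be >= 1", call. = FALSE)
  if (co2_ref_ppm <= 0) stop("reference concentration must be > 0", call. = FALSE)
  structure(
    list(
      co2_irf_a0 = co2_irf_a0, co2_irf_a = co2_irf_a,
      co2_irf_tau = co2_irf_tau, co2_per_ppm = co2_per_ppm,
      ch4_lifetime = ch4_lifetime, ch4_per_ppb = ch4_per_ppb,
      ch4_efficiency = ch4_efficiency, ch4_indirect = ch4_indirect,
      co2_forcing = co2_forcing, co2_eff_per_ppm = co2_eff_per_ppm,
      co2_ref_ppm = co2_ref_ppm, co2_log_alpha = co2_log_alpha
    ),
    class = "gas_cycle_params"
  )
}

#' Thermal response parameters
#'
#' Two-mode temperature impulse response
#' \eqn{R(t) = \sum_j (q_j/d_j) e^{-t/d_j}}: a fast mixed-layer mode and a
#' slow deep-ocean mode. A step forcing `F` asymptotes to
#' \eqn{F \sum_j q_j} (1.06 K per W/m2 with defaults).
#'
#' @param q Mode amplitudes (K per W/m2), both > 0.
#' @param d Mode time constants (years), `d[1] < d[2]`.
#' @return A list of class `thermal_params`.
#' @export
thermal_params <- function(q = c(0.631, 0.429), d = c(8.4, 409.5)) {
  if (length(q) != 2L || length(d) != 2L) {
    stop("exactly two thermal modes are required", call. = FALSE)
  }
  if (any(q <= 0) || any(d <= 0)) stop("q and d must be > 0", call. = FALSE)
  if (d[1L] >= d[2L]) stop("d[1] must be < d[2]", call. = FALSE)
  structure(list(q = q, d = d), class = "thermal_params")
}

#' Read emulator parameters from a YAML file
#'
#' The file may contain any subset of the argument names of
#' [gas_cycle_params()] plus `q` and `d` for [thermal_params()]; omitted
#' fields keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A [climate_emulator()] object.
#' @export
read_emulator_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  y <- yaml::read_yaml(path)
  thermal_fields <- intersect(names(y), c("q", "d"))
  gas_fields <- setdiff(names(y), thermal_fields)
  unknown <- setdiff(gas_fields, names(formals(gas_cycle_params)))
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  gc <- do.call(gas_cycle_params, lapply(y[gas_fields], unlist))
  th <- do.call(thermal_params, lapply(y[thermal_fields], unlist))
  climate_emulator(gas_cycle = gc, thermal = th)
}

#' Write emulator parameters to a YAML file
#'
#' @param emulator A [climate_emulator()] object.
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
write_emulator_params <- function(emulator, path) {
  stopifnot(inherits(emulator, "climate_emulator"))
  y <- c(unclass(emulator$gas_cycle), unclass(emulator$thermal))
  yaml::write_yaml(y, path)
  invisible(path)
}
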